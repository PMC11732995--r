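#' Trait-trait Pearson correlation half-matrix
#'
#' Pairwise-complete Pearson correlations between all trait pairs of a
#' genotype x trait table, the statistic compared between field data and
#' crop-model output.
#'
#' @param table data frame with one row per genotype and one numeric
#'   column per trait (non-trait columns ignored via `traits`).
#' @param traits trait column names; default all numeric columns.
#' @param min_n minimum complete observations per pair, default 3.
#' @return tibble `trait_a`, `trait_b` (a < b alphabetically), `r`, `n`;
#'   pairs with a constant trait or fewer than `min_n` complete rows get
#'   `r = NA`.
#' @export
corr_table <- function(table, traits = NULL, min_n = 3L) {
  table <- as.data.frame(table)
  if (is.null(traits)) {
    traits <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  stopifnot(length(traits) >= 2, all(traits %in% names(table)))
  traits <- sort(traits)
  out <- list(); k <- 0L
  for (i in seq_len(length(traits) - 1L)) {
    for (j in seq.int(i + 1L, length(traits))) {
      a <- table[[traits[i]]]; b <- table[[traits[j]]]
      ok <- !is.na(a) & !is.na(b)
      r <- NA_real_
      if (sum(ok) >= min_n && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
        r <- stats::cor(a[ok], b[ok])
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(trait_a = traits[i], trait_b = traits[j],
                                 r = r, n = sum(ok))
    }
  }
  dplyr::bind_rows(out)
}

#' Compare field and simulated correlation structures
#'
#' Joins two [corr_table()] outputs on shared trait pairs and classifies
#' each pair by its distance to the one-to-one line. The distance is the
#' perpendicular distance `|r_field - r_sim| / sqrt(2)` of the point
#' `(r_field, r_sim)` to the identity line; a pair is concordant when that
#' distance is below `d_max` and both correlations exceed `r_min` in
#' absolute value.
#'
#' @param field_corr,sim_corr [corr_table()] outputs.
#' @param d_max distance threshold, default 0.09.
#' @param r_min magnitude gate on both correlations, default 0.5.
#' @return tibble `trait_a`, `trait_b`, `r_field`, `r_sim`, `distance`,
#'   `concordant`.
#' @export
compare_correlations <- function(field_corr, sim_corr, d_max = 0.09,
                                 r_min = 0.5) {
  canon <- function(tb, what) {
    swap <- tb$trait_a > tb$trait_b
    tmp <- tb$trait_a[swap]
    tb$trait_a[swap] <- tb$trait_b[swap]
    tb$trait_b[swap] <- tmp
    tb <- tb[!is.na(tb$r), c("trait_a", "trait_b", "r")]
    names(tb)[3] <- what
    tb
  }
  j <- dplyr::inner_join(canon(field_corr, "r_field"),
                         canon(sim_corr, "r_sim"),
                         by = c("trait_a", "trait_b"))
  if (!nrow(j)) stop("no shared trait pairs between the two tables")
  dropped <- nrow(field_corr) - nrow(j)
  if (dropped > 0) {
    message(dropped, " field pair(s) without a simulated counterpart")
  }
  j$distance <- abs(j$r_field - j$r_sim) / sqrt(2)
  j$concordant <- j$distance < d_max & abs(j$r_field) > r_min &
    abs(j$r_sim) > r_min
  j
}
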