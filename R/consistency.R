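#' Standardized major axis fit
#'
#' Symmetric line fit for non-causal trait-trait relations where both axes
#' carry error: slope is `sign(r) * s_y / s_x`, the intercept passes through
#' the means, and the coefficient of determination equals the squared
#' Pearson correlation (identical for SMA and OLS).
#'
#' @param x,y paired numeric vectors; pairs with any missing value dropped.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @examples
#' sma_fit(1:10, 2 * (1:10))
#' @export
sma_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  if (r == 0) slope <- sy / sx  # sign convention for the degenerate case
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = r^2, n = length(x))
}

#' Pairwise trait consistency across growing conditions
#'
#' For one trait, computes the SMA coefficient of determination (`r2_sma`)
#' of genotype BLUEs between every unordered pair of growing conditions
#' with at least `min_n` shared genotypes (complete cases per pair).
#'
#' @param blue_table output of [build_blue_table()].
#' @param trait single trait name.
#' @param conditions optional subset of condition keys.
#' @param min_n minimum shared genotypes per pair, default 3.
#' @return tibble with `trait`, `condition_a`, `condition_b`, `r2_sma`, `n`.
#' @export
pairwise_consistency <- function(blue_table, trait, conditions = NULL,
                                 min_n = 3L) {
  bt <- blue_table[blue_table$trait == trait, ]
  if (!is.null(conditions)) bt <- bt[bt$condition %in% conditions, ]
  conds <- sort(unique(bt$condition))
  if (length(conds) < 2) stop("trait present in fewer than 2 conditions")
  wide <- tidyr::pivot_wider(bt[, c("genotype", "condition", "blue")],
                             names_from = "condition", values_from = "blue")
  m <- as.matrix(wide[, conds, drop = FALSE])
  out <- list(); k <- 0L
  for (i in seq_len(length(conds) - 1L)) {
    for (j in seq.int(i + 1L, length(conds))) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(ok) < min_n) next
      r <- stats::cor(m[ok, i], m[ok, j])
      k <- k + 1L
      out[[k]] <- tibble::tibble(trait = trait,
                                 condition_a = conds[i],
                                 condition_b = conds[j],
                                 r2_sma = r^2, n = sum(ok))
    }
  }
  dplyr::bind_rows(out)
}

#' Group consistency pairs by shared design factors
#'
#' A pair belongs to a level of the grouping iff both of its growing
#' conditions agree on every fixed factor; pairs whose conditions differ on
#' a fixed factor are dropped from that grouping. With `fixed_factors =
#' character(0)` all pairs are pooled into one level `"all"`. Double
#' groupings (e.g. `c("management", "location")`) key on the level
#' combination, so the surviving pairs differ only in the remaining factor.
#'
#' @param pairs output of [pairwise_consistency()].
#' @param fixed_factors subset of `c("year", "location", "management")`.
#' @return tibble `level`, `r2_sma`, `n` (one row per retained pair).
#' @export
group_pairs <- function(pairs, fixed_factors = character()) {
  stopifnot(all(fixed_factors %in% c("year", "location", "management")))
  a <- split_condition_key(pairs$condition_a)
  b <- split_condition_key(pairs$condition_b)
  if (!length(fixed_factors)) {
    return(tibble::tibble(level = "all", r2_sma = pairs$r2_sma, n = pairs$n))
  }
  keep <- rep(TRUE, nrow(pairs))
  for (f in fixed_factors) keep <- keep & (a[[f]] == b[[f]])
  lev <- do.call(paste, c(lapply(fixed_factors, function(f) {
    a[[f]][keep]
  }), sep = "-"))
  tibble::tibble(level = lev, r2_sma = pairs$r2_sma[keep], n = pairs$n[keep])
}

#' Summarise grouped consistency values
#'
#' Per level: maximum, mean and minimum `r2_sma`, plus a one-way ANOVA
#' across levels and Fisher LSD letters when requested.
#'
#' @param grouped output of [group_pairs()].
#' @param letters run [anova_lsd()] across levels (needs >= 2 levels with
#'   >= 2 values each)?
#' @param alpha significance level of the ANOVA gate.
#' @return tibble `level`, `n_pairs`, `max`, `mean`, `min`, `letter`, with
#'   attribute `anova_p`.
#' @export
summarise_consistency <- function(grouped, letters = TRUE, alpha = 0.05) {
  sm <- dplyr::summarise(dplyr::group_by(grouped, .data$level),
                         n_pairs = dplyr::n(),
                         max = max(.data$r2_sma),
                         mean = mean(.data$r2_sma),
                         min = min(.data$r2_sma), .groups = "drop")
  sm$letter <- NA_character_
  p <- NA_real_
  if (letters) {
    vals <- split(grouped$r2_sma, grouped$level)
    res <- tryCatch(anova_lsd(vals, alpha = alpha), error = function(e) NULL)
    if (!is.null(res)) {
      p <- res$anova_p
      sm$letter <- unname(res$letters[sm$level])
    }
  }
  attr(sm, "anova_p") <- p
  sm
}

#' One-way ANOVA with Fisher LSD letters
#'
#' Fixed-effects one-way ANOVA across levels; if the ANOVA p-value passes
#' `alpha`, all pairwise t-tests are performed with the pooled within-group
#' mean square and its degrees of freedom (unprotected Fisher LSD beyond
#' the ANOVA gate), and a compact letter display is built by
#' insert-and-absorb. If the gate fails, all levels share letter "a".
#'
#' @param values_by_level named list of numeric vectors.
#' @param alpha gate and pairwise significance level, default 0.05.
#' @return list with `anova_p` and `letters` (named by level).
#' @export
anova_lsd <- function(values_by_level, alpha = 0.05) {
  n_i <- vapply(values_by_level, length, 1L)
  drop <- n_i < 2
  if (any(drop)) {
    warning("level(s) with < 2 values excluded: ",
            paste(names(values_by_level)[drop], collapse = ", "),
            call. = FALSE)
    values_by_level <- values_by_level[!drop]
  }
  if (length(values_by_level) < 2) stop("need >= 2 levels with >= 2 values")
  y <- unlist(values_by_level, use.names = FALSE)
  g <- factor(rep(names(values_by_level),
                  vapply(values_by_level, length, 1L)),
              levels = names(values_by_level))
  av <- stats::anova(stats::aov(y ~ g))
  p <- av[["Pr(>F)"]][1]
  mse <- av[["Mean Sq"]][2]
  df <- av[["Df"]][2]
  means <- vapply(values_by_level, mean, numeric(1))
  ns <- vapply(values_by_level, length, 1L)
  k <- length(means)
  if (p >= alpha) {
    return(list(anova_p = p,
                letters = stats::setNames(rep("a", k), names(means))))
  }
  # pairwise LSD decisions: TRUE = significantly different
  diff_mat <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      tstat <- (means[i] - means[j]) /
        sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      pv <- 2 * stats::pt(-abs(tstat), df)
      diff_mat[i, j] <- diff_mat[j, i] <- pv < alpha
    }
  }
  list(anova_p = p, letters = letter_display(means, diff_mat))
}

# compact letter display: levels share a letter iff not significantly
# different. Letters are the maximal cliques of the "not different" graph
# (insert-and-absorb yields the same display; cliques make the iff property
# hold by construction), ordered so that "a" contains the largest mean.
letter_display <- function(means, diff_mat) {
  ord <- order(-means, names(means))
  nm <- names(means)[ord]
  compat <- !diff_mat[nm, nm, drop = FALSE]
  diag(compat) <- TRUE
  k <- length(nm)
  cliques <- list()
  extend <- function(R, P) {
    if (!length(P)) {
      if (!any(vapply(cliques, function(cl) all(R %in% cl), TRUE))) {
        cliques[[length(cliques) + 1L]] <<- sort(R)
      }
      return(invisible())
    }
    for (v in P) {
      extend(c(R, v), P[P > v & compat[v, P]])
    }
    # prune branches already covered by a found clique
    invisible()
  }
  extend(integer(), seq_len(k))
  # keep maximal cliques only
  maximal <- vapply(cliques, function(cl) {
    !any(vapply(cliques, function(other) {
      length(other) > length(cl) && all(cl %in% other)
    }, TRUE))
  }, TRUE)
  cliques <- cliques[maximal]
  cliques <- cliques[order(vapply(cliques, min, 1L))]
  out <- stats::setNames(rep("", k), nm)
  for (gi in seq_along(cliques)) {
    idx <- cliques[[gi]]
    out[idx] <- paste0(out[idx], letters[gi])
  }
  out[names(means)]
}
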