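#' Genotype x environment trait matrix
#'
#' Assembles, for one trait, the complete-case genotype x growing-condition
#' matrix of BLUEs on which the stability indices are defined: genotypes
#' with any missing cell across the chosen conditions are dropped (count
#' reported via a message), rows are ordered by genotype id.
#'
#' @param blue_table output of [build_blue_table()].
#' @param trait single trait name.
#' @param conditions optional subset of condition keys; default all with
#'   the trait.
#' @return numeric matrix (genotypes x conditions) with dimnames.
#' @export
build_trait_matrix <- function(blue_table, trait, conditions = NULL) {
  bt <- blue_table[blue_table$trait == trait, ]
  if (!is.null(conditions)) bt <- bt[bt$condition %in% conditions, ]
  conds <- sort(unique(bt$condition))
  if (length(conds) < 3) stop("need >= 3 conditions with trait ", trait)
  wide <- tidyr::pivot_wider(bt[, c("genotype", "condition", "blue")],
                             names_from = "condition", values_from = "blue")
  wide <- dplyr::arrange(wide, .data$genotype)
  m <- as.matrix(wide[, conds, drop = FALSE])
  rownames(m) <- wide$genotype
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message(sum(!complete), " genotype(s) dropped (incomplete across ",
            length(conds), " conditions)")
  }
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3) stop("< 3 genotypes with complete cases")
  m
}

#' Nine stability indices per genotype
#'
#' Computes, on a complete genotype x environment matrix `x` (G x E, row
#' means `xi.`, column means `x.j`, grand mean `x..`, environment effects
#' `e_j = x.j - x..`), the nine classical stability statistics:
#'
#' * `S2_xi` -- environmental variance (Roemer): row variance of the
#'   genotype across environments (static concept; small = stable).
#' * `b_i` -- coefficient of regression (Finlay-Wilkinson): slope of the
#'   genotype's values on `e_j`; 1 means average responsiveness.
#' * `s2_di` -- deviation mean squares (Eberhart-Russell, without the
#'   replicate error correction since BLUEs are the input): lack of fit of
#'   the Finlay-Wilkinson regression, denominator E - 2 (small = stable).
#' * `r2_i` -- coefficient of determination (Pinthus) of the same
#'   regression (large = variation tracks the environment).
#' * `W_i` -- ecovalence (Wricke): the genotype's share of the interaction
#'   sum of squares (small = stable).
#' * `sigma2_i` -- stability variance (Shukla), an unbiased rescaling of
#'   ecovalence; may be negative (small = stable).
#' * `D2_i` -- genotypic stability (Hanson): deviation from the minimal
#'   slope `b_min = min_k b_k` (small = stable).
#' * `P_i` -- genotypic superiority measure (Lin & Binns): mean squared
#'   distance from the best genotype in each environment, divided by 2E
#'   (small = close to the best everywhere).
#' * `S_i4` -- variance of corrected ranks (Nassar & Huehn): values are
#'   corrected to `x_ij - xi. + x..`, ranked within environment (mean rank
#'   on ties), and the rank variance taken per genotype (small = stable).
#'
#' @param x numeric G x E matrix with genotype rownames, G >= 3, E >= 3
#'   (E >= 2 tolerated; `s2_di` and `r2_i` then `NA`).
#' @return tibble with one row per genotype: `genotype`, `b_i`, `s2_di`,
#'   `r2_i`, `W_i`, `sigma2_i`, `D2_i`, `P_i`, `S2_xi`, `S_i4`, plus
#'   attributes `G` and `E`.
#' @examples
#' x <- matrix(rnorm(20, 50), 5, 4,
#'             dimnames = list(paste0("G", 1:5), paste0("E", 1:4)))
#' stability_indices(x)
#' @export
stability_indices <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("matrix must be complete; see build_trait_matrix()")
  G <- nrow(x); E <- ncol(x)
  if (G < 3 || E < 2) stop("need G >= 3 genotypes and E >= 2 environments")
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%03d", seq_len(G))
  xi. <- rowMeans(x)
  x.j <- colMeans(x)
  x.. <- mean(x)
  e <- x.j - x..
  see <- sum(e^2)
  dev <- x - xi.                      # row-centred values
  b_i <- as.vector(dev %*% e) / see
  resid <- dev - outer(b_i, e)
  s2_di <- if (E > 2) rowSums(resid^2) / (E - 2) else rep(NA_real_, G)
  ss_row <- rowSums(dev^2)
  r2_i <- b_i^2 * see / ss_row
  inter <- sweep(dev, 2, e)           # x_ij - xi. - x.j + x..
  W_i <- rowSums(inter^2)
  sigma2_i <- if (G > 2) {
    (G * (G - 1) * W_i - sum(W_i)) / ((G - 1) * (G - 2) * (E - 1))
  } else rep(NA_real_, G)
  b_min <- min(b_i)
  D2_i <- rowSums((dev - outer(rep(b_min, G), e))^2)
  M_j <- apply(x, 2, max)
  P_i <- rowSums(sweep(x, 2, M_j)^2) / (2 * E)
  corrected <- dev + x..              # x_ij - xi. + x..
  # 12-significant-digit rounding restores ties that floating-point noise
  # would otherwise break (an additive matrix must rank all-tied)
  ranks <- apply(signif(corrected, 12), 2, rank)  # ties -> mean rank
  S_i4 <- apply(ranks, 1, stats::var)
  S2_xi <- ss_row / (E - 1)
  out <- tibble::tibble(genotype = rownames(x), b_i = unname(b_i),
                        s2_di = unname(s2_di), r2_i = unname(r2_i),
                        W_i = unname(W_i), sigma2_i = unname(sigma2_i),
                        D2_i = unname(D2_i), P_i = unname(P_i),
                        S2_xi = unname(S2_xi), S_i4 = unname(S_i4))
  attr(out, "G") <- G
  attr(out, "E") <- E
  out
}

#' Direction-of-stability metadata for the nine indices
#'
#' For each index: whether a smaller value means a more stable (or, for
#' `P_i`, more superior) genotype. `b_i` is directional around 1 (slopes
#' below 1 indicate static-type insensitivity) and `r2_i` is largest when
#' variation is fully explained by the environment, so neither has a
#' "smaller is stabler" reading.
#'
#' @return tibble `index`, `concept` (static/dynamic), `stable_when`.
#' @export
si_direction <- function() {
  tibble::tibble(
    index = c("b_i", "s2_di", "r2_i", "W_i", "sigma2_i", "D2_i", "P_i",
              "S2_xi", "S_i4"),
    concept = c("dynamic", "dynamic", "dynamic", "dynamic", "dynamic",
                "static", "dynamic", "static", "static"),
    stable_when = c("near 1 (below 1: static-type)", "smaller",
                    "larger (environment-tracking)", "smaller", "smaller",
                    "smaller", "smaller", "smaller", "smaller"))
}

#' Genotype-level total fungal infection regressor
#'
#' The pathogen term of the stability decomposition: by default the
#' genotype mean of TFI BLUEs over the chosen conditions (`mode =
#' "mean_tfi"`); alternatively the chosen stability index applied to the
#' genotype x condition TFI matrix (`mode = "si_of_tfi"`).
#'
#' @param blue_table output of [build_blue_table()] containing trait `TFI`.
#' @param genotypes genotype ids to report (order preserved).
#' @param conditions optional condition subset.
#' @param mode `"mean_tfi"` or `"si_of_tfi"`.
#' @param si_name index column used when `mode = "si_of_tfi"`.
#' @return named numeric vector over `genotypes` (NA when a genotype has no
#'   TFI data).
#' @export
tfi_regressor <- function(blue_table, genotypes, conditions = NULL,
                          mode = c("mean_tfi", "si_of_tfi"),
                          si_name = "W_i") {
  mode <- match.arg(mode)
  bt <- blue_table[blue_table$trait == "TFI", ]
  if (!is.null(conditions)) bt <- bt[bt$condition %in% conditions, ]
  if (!nrow(bt)) stop("no TFI entries in the BLUE table")
  if (mode == "mean_tfi") {
    mns <- vapply(split(bt$blue, bt$genotype), mean, numeric(1))
    return(stats::setNames(unname(mns[genotypes]), genotypes))
  }
  m <- build_trait_matrix(blue_table, "TFI", conditions)
  st <- stability_indices(m)
  v <- stats::setNames(st[[si_name]], st$genotype)
  stats::setNames(unname(v[genotypes]), genotypes)
}

#' Stability-of-yield decomposition for one index
#'
#' Regresses, across genotypes, the stability of the response trait on the
#' stabilities of the component traits plus the total fungal infection
#' term: `SI_GY = SI_TGW + SI_HI + SI_Straw + SI_GpS + SI_SN + TFI + e`,
#' OLS with intercept. Genotypes with any missing regressor are dropped;
#' constant regressors are dropped with a warning.
#'
#' @param stability_tables named list (by trait) of [stability_indices()]
#'   outputs; must include the response trait.
#' @param si_name which index column to regress (one of the nine).
#' @param tfi named vector from [tfi_regressor()], or `NULL` to omit the
#'   pathogen term.
#' @param response trait name of the response stability.
#' @return tibble as [bp_regression()]: `level` (= `si_name`),
#'   `n_conditions` (here the genotype count), `term`, `estimate`,
#'   `p_value`, `stars`, `r2_full`.
#' @export
si_regression <- function(stability_tables, si_name, tfi = NULL,
                          response = "Seedyield") {
  stopifnot(response %in% names(stability_tables))
  traits <- names(stability_tables)
  common <- Reduce(intersect, lapply(stability_tables,
                                     function(t) t$genotype))
  if (!is.null(tfi)) common <- intersect(common, names(tfi)[!is.na(tfi)])
  if (length(common) < length(traits) + 3) {
    stop("too few genotypes shared across stability tables")
  }
  d <- tibble::tibble(genotype = common)
  for (tr in traits) {
    t_ <- stability_tables[[tr]]
    d[[tr]] <- t_[[si_name]][match(common, t_$genotype)]
  }
  if (!is.null(tfi)) d[["TFI"]] <- unname(tfi[common])
  regressors <- c(setdiff(traits, response),
                  if (!is.null(tfi)) "TFI")
  d <- d[stats::complete.cases(d), ]
  fit_importance_lm(d, response, regressors, level = si_name)
}
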