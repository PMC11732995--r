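#' LMG relative importance of regressors
#'
#' Decomposes the R-squared of an OLS regression with intercept into
#' nonnegative per-regressor shares by averaging each regressor's
#' sequential R-squared gain over all orders of entry (the LMG /
#' averaging-over-orderings decomposition). Computed by the equivalent
#' subset-weighted formula
#' `share_k = sum over S not containing k of
#'  |S|! (p - |S| - 1)! / p! * (R2(S + k) - R2(S))`,
#' with exhaustive enumeration of all `2^p` subsets.
#'
#' @param y numeric response vector.
#' @param X data frame or matrix of regressors (p <= 10); constant columns
#'   are an error (drop them first), as is rank deficiency.
#' @return list with `shares` (named, summing to `r2_full`), `r2_full`,
#'   `method = "lmg"`, `p`, `n`.
#' @examples
#' set.seed(1)
#' X <- data.frame(a = rnorm(50), b = rnorm(50))
#' y <- X$a + 0.5 * X$b + rnorm(50)
#' lmg(y, X)$shares
#' @export
lmg <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  stopifnot(p >= 1, p <= 10)
  keep <- stats::complete.cases(X) & !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n <= p + 1) stop("need n > p + 1 observations")
  Xm <- as.matrix(X)
  if (any(apply(Xm, 2, stats::sd) == 0)) {
    stop("constant regressor column(s): ",
         paste(colnames(Xm)[apply(Xm, 2, stats::sd) == 0], collapse = ", "))
  }
  if (qr(cbind(1, Xm))$rank < p + 1) {
    stop("rank-deficient regressor set (collinear columns among: ",
         paste(colnames(Xm), collapse = ", "), ")")
  }
  tss <- sum((y - mean(y))^2)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    fit <- stats::lm.fit(cbind(1, Xm[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / tss
  }
  # R2 of every subset, indexed by bitmask
  nsub <- 2L^p
  r2 <- numeric(nsub)
  for (mask in seq_len(nsub - 1L)) {
    r2[mask + 1L] <- r2_of(which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0))
  }
  sizes <- vapply(0:(nsub - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0), 1L)
  wt <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  shares <- numeric(p)
  for (k in seq_len(p)) {
    bit <- bitwShiftL(1L, k - 1L)
    for (m in 0:(nsub - 1L)) {
      if (bitwAnd(m, bit) == 0L) {
        s <- sizes[m + 1L]
        shares[k] <- shares[k] +
          wt[s + 1L] * (r2[bitwOr(m, bit) + 1L] - r2[m + 1L])
      }
    }
  }
  names(shares) <- colnames(Xm)
  list(shares = shares, r2_full = r2[nsub], method = "lmg", p = p, n = n)
}

#' Stack LMG results for reporting
#'
#' Long table backing a stacked-bar rendering of relative importance: one
#' row per (model label, regressor), with shares on the R-squared scale
#' (summing per label to that model's full R-squared) and additionally
#' normalised to proportions of R-squared.
#'
#' @param models list of `list(label = , lmg = )` pairs, or a named list of
#'   [lmg()] results (names become labels).
#' @return tibble `label`, `regressor`, `share`, `share_of_r2`, `r2_full`.
#' @export
stacked_importance <- function(models) {
  if (!length(models)) {
    return(tibble::tibble(label = character(), regressor = character(),
                          share = numeric(), share_of_r2 = numeric(),
                          r2_full = numeric()))
  }
  if (!is.null(names(models)) && all(nzchar(names(models)))) {
    models <- lapply(seq_along(models), function(i) {
      list(label = names(models)[i], lmg = models[[i]])
    })
  }
  dplyr::bind_rows(lapply(models, function(m) {
    tibble::tibble(label = m$label,
                   regressor = names(m$lmg$shares),
                   share = unname(m$lmg$shares),
                   share_of_r2 = unname(m$lmg$shares) / m$lmg$r2_full,
                   r2_full = m$lmg$r2_full)
  }))
}
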