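#' Best linear unbiased estimates of cultivar means for one condition
#'
#' Fits, within a single growing condition, the model
#' `y_irc = mu + g_i + R_r + C_c` with genotype fixed effects and
#' independent row and column random intercepts (REML), accounting for
#' uneven soil-fertility gradients across the field grid. The BLUE of
#' genotype i is `mu + g_i` under sum-to-zero genotype coding, i.e. the
#' model-adjusted genotype mean on the observation scale.
#'
#' When the layout is unusable (row or column missing for more than half
#' the plots, or fewer than two distinct levels of both) or the REML fit
#' fails to converge, the fit falls back to per-genotype arithmetic means
#' and flags `fallback = "means"`.
#'
#' @param records plot-record tibble.
#' @param trait single trait name.
#' @param condition a `"year/location/management"` key.
#' @return a `blue_fit`: list with `mu`, `g` (named genotype effects),
#'   `blues` (named, `mu + g`), `var_row`, `var_col`, `var_resid`, `n_obs`,
#'   `converged`, `fallback` (`"none"` or `"means"`).
#' @export
fit_blues <- function(records, trait, condition) {
  records <- as_plot_records(records)
  ck <- split_condition_key(condition)
  d <- records[records$trait == trait & records$year == ck$year &
                 records$location == ck$location &
                 records$management == ck$management &
                 !is.na(records$value), ]
  if (!nrow(d)) stop("no non-missing observations for ", trait, " in ",
                     condition)
  fit_blues_df(d)
}

# workhorse on a prefiltered (one trait x one condition) data frame
fit_blues_df <- function(d) {
  genos <- sort(unique(d$genotype))
  if (length(genos) < 2) stop("need >= 2 genotypes with observations")
  means <- vapply(split(d$value, d$genotype), mean, numeric(1))[genos]
  means_fit <- function(converged) {
    mu <- mean(means)
    structure(list(mu = mu, g = means - mu, blues = means,
                   var_row = NA_real_, var_col = NA_real_,
                   var_resid = stats::var(d$value -
                                            means[d$genotype]) %||% NA_real_,
                   n_obs = nrow(d), converged = converged,
                   fallback = "means"), class = "blue_fit")
  }
  layout_missing <- mean(is.na(d$row) | is.na(d$col)) > 0.5
  dd <- d[!is.na(d$row) & !is.na(d$col), ]
  if (layout_missing || length(unique(dd$row)) < 2 ||
      length(unique(dd$col)) < 2 || nrow(dd) <= length(genos)) {
    return(means_fit(converged = TRUE))
  }
  dd$genotype <- factor(dd$genotype, levels = genos)
  dd$row_f <- factor(dd$row)
  dd$col_f <- factor(dd$col)
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE, check.conv.singular = "ignore",
    optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8, maxeval = 200))
  fit_terms <- function(terms) {
    fml <- stats::reformulate(c("0", "genotype", terms),
                              response = "value")
    tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = dd, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
  }
  full <- fit_terms(c("(1 | row_f)", "(1 | col_f)"))
  if (is.null(full)) return(means_fit(converged = FALSE))
  # retain a variance component only when the data support it: restricted
  # likelihood ratio against the model without it, boundary-corrected
  # 0.5 * chi2(1) reference; unsupported components are dropped and a fit
  # with no surviving component collapses to the genotype means
  vc_full <- as.data.frame(lme4::VarCorr(full))
  ll_full <- as.numeric(stats::logLik(full))
  keep <- character()
  reduced <- list(row_f = "(1 | col_f)", col_f = "(1 | row_f)")
  for (comp in c("row_f", "col_f")) {
    if (vc_full$vcov[vc_full$grp == comp] <= 0) next
    red <- fit_terms(reduced[[comp]])
    if (is.null(red)) { keep <- c(keep, comp); next }
    stat <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red))))
    p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
    if (p < 0.05) keep <- c(keep, comp)
  }
  if (!length(keep)) return(means_fit(converged = TRUE))
  fit <- if (length(keep) == 2) full else {
    fit_terms(sprintf("(1 | %s)", keep))
  }
  if (is.null(fit)) return(means_fit(converged = FALSE))
  blues <- lme4::fixef(fit)
  names(blues) <- sub("^genotype", "", names(blues))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(nm) {
    v <- vc$vcov[vc$grp == nm]
    if (length(v)) v else 0
  }
  # genotypes observed only on plots without layout keep their raw mean
  blues <- blues[!is.na(blues)]
  missing_g <- setdiff(genos, names(blues))
  if (length(missing_g)) blues <- c(blues, means[missing_g])[genos]
  mu <- mean(blues)
  structure(list(mu = mu, g = blues - mu, blues = blues,
                 var_row = getv("row_f"), var_col = getv("col_f"),
                 var_resid = getv("Residual"), n_obs = nrow(dd),
                 converged = TRUE, fallback = "none"),
            class = "blue_fit")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Build the genotype x condition x trait BLUE table
#'
#' Applies [fit_blues()] per (trait, growing condition) cell; cells with no
#' data are skipped. One row per genotype with at least one observation in
#' the cell.
#'
#' @param records cleaned plot-record tibble.
#' @param traits trait names to fit; default all traits present.
#' @param conditions condition keys to fit; default all present.
#' @param quiet suppress the per-cell progress message.
#' @return tibble with columns `genotype`, `year`, `location`, `management`,
#'   `condition`, `trait`, `blue`, `fallback`.
#' @export
build_blue_table <- function(records, traits = NULL, conditions = NULL,
                             quiet = TRUE) {
  records <- as_plot_records(records)
  records$condition <- condition_key(records$year, records$location,
                                     records$management)
  if (is.null(traits)) traits <- sort(unique(records$trait))
  if (is.null(conditions)) conditions <- sort(unique(records$condition))
  records <- records[records$trait %in% traits &
                       records$condition %in% conditions &
                       !is.na(records$value), ]
  cells <- split(records,
                 list(trait = records$trait, condition = records$condition),
                 drop = TRUE)
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    d <- cells[[i]]
    if (length(unique(d$genotype)) < 2) next
    f <- fit_blues_df(d)
    if (!quiet) {
      message(d$trait[1], " @ ", d$condition[1], ": ", f$fallback,
              if (!f$converged) " (non-convergent)")
    }
    out[[i]] <- tibble::tibble(
      genotype = names(f$blues), year = d$year[1], location = d$location[1],
      management = d$management[1], condition = d$condition[1],
      trait = d$trait[1], blue = unname(f$blues), fallback = f$fallback)
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$trait, .data$condition, .data$genotype)
}
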