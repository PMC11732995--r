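#' Breeding progress of one trait in one growing condition
#'
#' Breeding progress (BP) is the slope of the ordinary least squares
#' regression of cultivar BLUEs on cultivar year of release, in trait units
#' per release year, within one growing condition.
#'
#' @param blue_table output of [build_blue_table()].
#' @param meta cultivar metadata tibble (`genotype`, `release_year`); see
#'   [read_cultivar_meta()].
#' @param trait single trait name.
#' @param condition a `"year/location/management"` key.
#' @param panel optional genotype subset (e.g. the cultivars representing
#'   the breeding history); default all genotypes in the table.
#' @return tibble row: `trait`, `condition`, `bp` (slope), `p_value`, `r2`,
#'   `n`.
#' @export
estimate_bp <- function(blue_table, meta, trait, condition, panel = NULL) {
  bt <- blue_table[blue_table$trait == trait &
                     blue_table$condition == condition, ]
  if (!is.null(panel)) bt <- bt[bt$genotype %in% panel, ]
  d <- dplyr::inner_join(bt[, c("genotype", "blue")],
                         meta[, c("genotype", "release_year")],
                         by = "genotype")
  d <- d[!is.na(d$blue) & !is.na(d$release_year), ]
  if (nrow(d) < 3) stop("need >= 3 genotypes with BLUE and release year")
  if (stats::sd(d$release_year) == 0) stop("all release years equal")
  fit <- stats::lm(blue ~ release_year, data = d)
  sm <- summary(fit)
  tibble::tibble(trait = trait, condition = condition,
                 bp = unname(stats::coef(fit)["release_year"]),
                 p_value = sm$coefficients["release_year", "Pr(>|t|)"],
                 r2 = sm$r.squared, n = nrow(d))
}

#' Breeding progress for every trait x condition combination
#'
#' @inheritParams estimate_bp
#' @param traits trait names; default all in the table.
#' @param conditions condition keys; default all in the table.
#' @return tibble of [estimate_bp()] rows; cells that cannot be estimated
#'   (too few genotypes, no release-year spread) are skipped.
#' @export
bp_table <- function(blue_table, meta, traits = NULL, conditions = NULL,
                     panel = NULL) {
  if (is.null(traits)) traits <- sort(unique(blue_table$trait))
  if (is.null(conditions)) {
    conditions <- sort(unique(blue_table$condition))
  }
  out <- list()
  for (tr in traits) {
    for (cd in conditions) {
      row <- tryCatch(estimate_bp(blue_table, meta, tr, cd, panel),
                      error = function(e) NULL)
      if (!is.null(row)) out[[length(out) + 1L]] <- row
    }
  }
  dplyr::bind_rows(out)
}

#' Multi-linear decomposition of grain-yield breeding progress
#'
#' Regresses, across growing conditions, the BP of a response trait
#' (typically grain yield) on the BPs of component traits:
#' `BP_GY = BP_TGW + BP_HI + BP_Straw + BP_GpS + BP_SN + e`,
#' with an intercept; each growing condition contributes one observation.
#' One model is fitted per grouping level plus a pooled `"all"` model;
#' levels with fewer conditions than regressors + 2 are skipped with a
#' warning, and regressors constant within a level are dropped with a
#' warning.
#'
#' @param bp per-condition BP estimates from [bp_table()].
#' @param response trait name of the response BP.
#' @param regressors trait names of the component BPs.
#' @param grouping `NULL` (pooled only) or one of `"year"`, `"location"`,
#'   `"management"` (levels plus pooled).
#' @return tibble with one row per (level, term): `level`, `n_conditions`,
#'   `term`, `estimate`, `p_value`, `stars`, `r2_full`.
#' @export
bp_regression <- function(bp, response = "Seedyield",
                          regressors = c("TGW", "Harvest_Index_bio",
                                         "Straw", "Grain_per_spike_bio",
                                         "Spike_number_bio"),
                          grouping = NULL) {
  wide <- tidyr::pivot_wider(bp[, c("condition", "trait", "bp")],
                             names_from = "trait", values_from = "bp")
  need <- c(response, regressors)
  miss <- setdiff(need, names(wide))
  if (length(miss)) stop("BP not available for trait(s): ",
                         paste(miss, collapse = ", "))
  wide <- wide[stats::complete.cases(wide[, need]), ]
  fac <- split_condition_key(wide$condition)
  levels_ <- list(all = rep(TRUE, nrow(wide)))
  if (!is.null(grouping)) {
    stopifnot(grouping %in% c("year", "location", "management"))
    for (lv in sort(unique(as.character(fac[[grouping]])))) {
      levels_[[lv]] <- as.character(fac[[grouping]]) == lv
    }
  }
  out <- list()
  for (lv in names(levels_)) {
    d <- wide[levels_[[lv]], ]
    if (nrow(d) < length(regressors) + 2) {
      warning("grouping level '", lv, "' skipped: only ", nrow(d),
              " conditions", call. = FALSE)
      next
    }
    out[[lv]] <- fit_importance_lm(d, response, regressors, level = lv)
  }
  dplyr::bind_rows(out)
}

# shared OLS machinery for the BP and SI decompositions: drops constant
# columns, fits with intercept, returns tidy coefficients
fit_importance_lm <- function(d, response, regressors, level = "all") {
  keep <- regressors[vapply(regressors,
                            function(v) stats::sd(d[[v]]) > 0, TRUE)]
  dropped <- setdiff(regressors, keep)
  if (length(dropped)) {
    warning("constant regressor(s) dropped in level '", level, "': ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(keep)) stop("no non-constant regressors in level ", level)
  fml <- stats::reformulate(paste0("`", keep, "`"),
                            response = paste0("`", response, "`"))
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  term <- rownames(co)
  term <- gsub("`", "", term)
  tibble::tibble(level = level, n_conditions = nrow(d), term = term,
                 estimate = unname(co[, "Estimate"]),
                 p_value = unname(co[, "Pr(>|t|)"]),
                 stars = unname(p_stars(co[, "Pr(>|t|)"])),
                 r2_full = sm$r.squared)
}

#' Significance stars
#' @param p numeric p-values.
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   `""` otherwise.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
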