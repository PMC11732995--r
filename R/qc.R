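#' Range rule for plot-level quality control
#'
#' Values outside `[min_valid, max_valid]` are recoded to missing (never
#' deleted). Negative values are additionally recoded for traits flagged
#' nonnegative in the registry.
#'
#' @param trait registry trait name.
#' @param min_valid,max_valid bounds; `-Inf`/`Inf` leave a side open.
#' @return a `range_rule` list.
#' @export
range_rule <- function(trait, min_valid = -Inf, max_valid = Inf) {
  stopifnot(min_valid < max_valid)
  structure(list(trait = trait, min_valid = min_valid,
                 max_valid = max_valid), class = "range_rule")
}

#' Default range rules
#'
#' Ships the two published implausibility bounds: grain yield above
#' 3000 dt/ha and thousand grain weight above 80 g are recoded missing.
#' Observed trait ranges are deliberately not used as bounds.
#' @return list of [range_rule()]s.
#' @export
default_range_rules <- function() {
  list(range_rule("Seedyield", max_valid = 3000),
       range_rule("TGW", max_valid = 80))
}

#' Recode out-of-range values to missing
#'
#' @param records plot-record tibble.
#' @param rules list of [range_rule()]s.
#' @param registry trait registry; traits with `nonnegative = TRUE` get
#'   negative values recoded regardless of `rules`.
#' @return list with `records` (same rows, offending values `NA`) and
#'   `n_recoded`.
#' @export
apply_range_rules <- function(records, rules = default_range_rules(),
                              registry = trait_registry()) {
  records <- as_plot_records(records)
  known <- unique(records$trait)
  bad <- rep(FALSE, nrow(records))
  for (r in rules) {
    if (!r$trait %in% registry$trait) {
      stop("range rule references unknown trait: ", r$trait)
    }
    hit <- records$trait == r$trait & !is.na(records$value) &
      (records$value < r$min_valid | records$value > r$max_valid)
    bad <- bad | hit
  }
  nonneg <- registry$trait[registry$nonnegative]
  bad <- bad | (records$trait %in% nonneg & !is.na(records$value) &
                  records$value < 0)
  records$value[bad] <- NA_real_
  list(records = records, n_recoded = sum(bad))
}

#' Four-sigma outlier rule
#'
#' Within each growing condition, an observation of a listed trait lying
#' beyond the condition mean plus or minus `k` standard deviations is
#' excluded (the record is dropped, unlike range recoding). By default the
#' rule applies only to harvest index and spike number.
#'
#' @param traits trait names subject to the rule.
#' @param k sd multiplier (> 0), default 4.
#' @return an `sd_rule` list.
#' @export
sd_rule <- function(traits = c("Harvest_Index_bio", "Spike_number_bio"),
                    k = 4) {
  stopifnot(k > 0, length(traits) >= 1)
  structure(list(traits = traits, k = k), class = "sd_rule")
}

#' Exclude per-condition outliers beyond mean +/- k sd
#'
#' The sample standard deviation (n - 1 denominator) is computed per
#' (growing condition, trait) over all non-missing observations; groups with
#' fewer than 3 values are skipped with a message. Offending observations of
#' the rule's traits are removed from the table.
#'
#' @param records plot-record tibble.
#' @param rule an [sd_rule()].
#' @return list with `records` (offending rows dropped) and `n_excluded`.
#' @export
apply_sd_rule <- function(records, rule = sd_rule()) {
  records <- as_plot_records(records)
  idx <- which(records$trait %in% rule$traits & !is.na(records$value))
  if (!length(idx)) return(list(records = records, n_excluded = 0L))
  sub <- records[idx, ]
  grp <- paste(condition_key(sub$year, sub$location, sub$management),
               sub$trait, sep = "\r")
  n <- stats::ave(sub$value, grp, FUN = length)
  mu <- stats::ave(sub$value, grp, FUN = mean)
  sd_ <- stats::ave(sub$value, grp, FUN = stats::sd)
  skipped <- n < 3
  if (any(skipped)) {
    message("sd rule: ", length(unique(grp[skipped])),
            " condition-trait group(s) with < 3 values skipped")
  }
  out <- !skipped & abs(sub$value - mu) > rule$k * sd_
  out[is.na(out)] <- FALSE
  drop <- idx[out]
  list(records = if (length(drop)) records[-drop, ] else records,
       n_excluded = length(drop))
}

#' Total fungal infection per plot
#'
#' Adds a derived trait `TFI`, the sum of the six disease scores of a plot
#' (stripe rust, Septoria, powdery mildew, leaf rust, leaf tan spot,
#' Fusarium head blight), assuming infected areas are additive. Under the
#' strict default policy a plot with any missing component gets a missing
#' TFI; `na_rm = TRUE` instead sums the available components.
#'
#' @param records plot-record tibble containing the disease traits.
#' @param na_rm sum available components instead of propagating missingness.
#' @return the records with one added `TFI` row per plot that has at least
#'   one disease observation.
#' @export
compute_tfi <- function(records, na_rm = FALSE) {
  records <- as_plot_records(records)
  dz <- records[records$trait %in% disease_traits(), ]
  if (!nrow(dz)) stop("no disease observations present")
  key_cols <- c("genotype", "release_year", "year", "location", "management",
                "replicate", "row", "col")
  tfi <- dplyr::summarise(
    dplyr::group_by(dz, dplyr::across(dplyr::all_of(key_cols))),
    value = if (na_rm) sum(.data$value, na.rm = TRUE) else {
      if (dplyr::n() < 6L || anyNA(.data$value)) NA_real_
      else sum(.data$value)
    },
    .groups = "drop")
  tfi$trait <- "TFI"
  dplyr::bind_rows(records[records$trait != "TFI", ], as_plot_records(tfi))
}

#' Run the full QC stage
#'
#' Applies range recoding, the per-condition four-sigma exclusion and TFI
#' construction in that order, returning the cleaned records plus a report.
#'
#' @param records plot-record tibble.
#' @param range_rules list of [range_rule()]s.
#' @param sd_rules an [sd_rule()].
#' @param tfi add the TFI trait (requires disease observations)?
#' @param tfi_na_rm policy for missing TFI components, see [compute_tfi()].
#' @param registry trait registry.
#' @return list with `records` and `report` (tibble of step, n).
#' @export
qc_pipeline <- function(records, range_rules = default_range_rules(),
                        sd_rules = sd_rule(), tfi = TRUE, tfi_na_rm = FALSE,
                        registry = trait_registry()) {
  r1 <- apply_range_rules(records, range_rules, registry)
  r2 <- apply_sd_rule(r1$records, sd_rules)
  recs <- r2$records
  if (tfi && any(recs$trait %in% disease_traits())) {
    recs <- compute_tfi(recs, na_rm = tfi_na_rm)
  }
  list(records = recs,
       report = tibble::tibble(
         step = c("range_recoded", "sd_excluded"),
         n = c(r1$n_recoded, r2$n_excluded)))
}
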