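#' Trait registry
#'
#' The controlled vocabulary of plot-level traits: trait name as used in the
#' data, full name, sampling source ("50 cm cut", "whole plot" or "derived"),
#' unit, whether the trait is a fungal disease score (bounded 0-100), and
#' whether negative values are physically impossible. The registry shipped
#' with the package covers the 24 standard winter-wheat MET traits plus the
#' derived total fungal infection score; users may extend it by passing their
#' own data frame wherever a `registry` argument is accepted.
#'
#' @param extra optional data frame with the same columns, appended to the
#'   shipped registry (duplicated trait names in `extra` override).
#' @return a tibble with columns `trait`, `full_name`, `source`, `unit`,
#'   `is_disease`, `nonnegative`.
#' @export
trait_registry <- function(extra = NULL) {
  path <- system.file("extdata", "trait_registry.csv", package = "metgxe")
  reg <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  reg$is_disease <- as.logical(reg$is_disease)
  reg$nonnegative <- as.logical(reg$nonnegative)
  if (!is.null(extra)) {
    stopifnot(all(names(reg) %in% names(extra)))
    extra <- tibble::as_tibble(extra)[, names(reg)]
    reg <- dplyr::bind_rows(reg[!reg$trait %in% extra$trait, ], extra)
  }
  reg
}

#' Names of the six fungal disease score traits
#' @return character vector of the six disease trait names summed into TFI.
#' @export
disease_traits <- function() {
  c("Stripe_rust", "Septoria", "Powdery_mildew", "Leaf_rust", "DTR", "Fusarium")
}

# The nine management labels observed in the trial network: the full
# nitrogen x fungicide cross under rain-fed, the same cross irrigated, and
# one rain-out shelter treatment.
OBSERVED_MANAGEMENTS <- c(
  "HN_WF_RF", "HN_NF_RF", "LN_WF_RF", "LN_NF_RF",
  "HN_WF_IR", "HN_NF_IR", "LN_WF_IR", "LN_NF_IR",
  "HN_WF_RO"
)

#' Observed management labels
#'
#' The nine nitrogen/fungicide/water combinations realised in the trial
#' design: `HN`/`LN` (220 / 110 kg N per ha), `WF`/`NF` (with / without
#' fungicide), `RF`/`IR`/`RO` (rain-fed / irrigated / rain-out shelter).
#' @return character vector of nine labels such as `"HN_WF_RF"`.
#' @export
management_labels <- function() OBSERVED_MANAGEMENTS

#' Parse management labels into treatment components
#'
#' @param label character vector of labels like `"HN_WF_RF"`.
#' @param observed_only reject structurally valid labels that were never
#'   realised in the design (e.g. `"LN_NF_RO"`)? Default `TRUE`.
#' @return tibble with columns `label`, `nitrogen`, `fungicide`, `water`.
#' @examples
#' parse_management("HN_WF_RF")
#' @export
parse_management <- function(label, observed_only = TRUE) {
  parts <- strsplit(as.character(label), "_", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 3L
  if (!all(ok)) {
    stop("malformed management label(s): ",
         paste(unique(label[!ok]), collapse = ", "))
  }
  m <- do.call(rbind, parts)
  bad <- !(m[, 1] %in% c("HN", "LN")) | !(m[, 2] %in% c("WF", "NF")) |
    !(m[, 3] %in% c("RF", "IR", "RO"))
  if (observed_only) bad <- bad | !(label %in% OBSERVED_MANAGEMENTS)
  if (any(bad)) {
    stop("unknown management label(s): ",
         paste(unique(label[bad]), collapse = ", "))
  }
  tibble::tibble(label = as.character(label),
                 nitrogen = m[, 1], fungicide = m[, 2], water = m[, 3])
}

#' Build a management label from its components
#' @param nitrogen `"HN"` or `"LN"`; @param fungicide `"WF"` or `"NF"`;
#' @param water `"RF"`, `"IR"` or `"RO"`.
#' @return the underscore-joined label.
#' @export
management_label <- function(nitrogen, fungicide, water) {
  lab <- paste(nitrogen, fungicide, water, sep = "_")
  parse_management(lab, observed_only = FALSE)  # validates components
  lab
}

#' Growing-condition key
#'
#' A growing condition is one year x location x management combination; its
#' key is the slash-joined string `"2015/GGE/HN_WF_RF"`.
#' @param year,location,management vectors (recycled).
#' @return character vector of keys.
#' @export
condition_key <- function(year, location, management) {
  paste(year, location, management, sep = "/")
}

#' Split growing-condition keys back into components
#' @param key character vector of `"year/location/management"` keys.
#' @return tibble with columns `condition`, `year`, `location`, `management`.
#' @export
split_condition_key <- function(key) {
  parts <- strsplit(as.character(key), "/", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 3L)) stop("malformed condition key")
  m <- do.call(rbind, parts)
  tibble::tibble(condition = as.character(key),
                 year = as.integer(m[, 1]), location = m[, 2],
                 management = m[, 3])
}

# canonical long-format columns for a plot-record table
PLOT_COLUMNS <- c("genotype", "release_year", "year", "location", "management",
                  "replicate", "row", "col", "trait", "value")

#' Construct a plot-record table
#'
#' The canonical internal format is long ("tidy"): one row per plot x trait
#' observation, with columns `genotype`, `release_year`, `year`, `location`,
#' `management`, `replicate`, `row`, `col`, `trait`, `value`. `release_year`,
#' `row` and `col` may be missing.
#'
#' @param df a data frame carrying at least `genotype`, `year`, `location`,
#'   `management`, `trait`, `value`.
#' @return tibble in canonical column order, integer-typed where applicable.
#' @export
as_plot_records <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("genotype", "year", "location", "management", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  for (col in setdiff(PLOT_COLUMNS, names(df))) df[[col]] <- NA
  df$genotype <- as.character(df$genotype)
  df$location <- as.character(df$location)
  df$management <- as.character(df$management)
  df$trait <- as.character(df$trait)
  for (col in c("release_year", "year", "replicate", "row", "col")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$value <- as.numeric(df$value)
  df[, PLOT_COLUMNS]
}

#' Read a plot-level MET table from CSV
#'
#' Accepts either the canonical long format (columns `trait` and `value`
#' present after renaming) or a wide per-plot layout with one column per
#' trait; wide tables are pivoted so every non-missing trait cell becomes
#' one record. Malformed numeric cells become `NA` with a warning.
#'
#' @param path CSV file (RFC 4180, UTF-8, "." decimal separator).
#' @param column_map named character vector or YAML file path translating
#'   canonical field names to source headers, e.g.
#'   `c(genotype = "BRISONr", year = "Year")`. Unmapped canonical names are
#'   assumed to equal the source header.
#' @param registry trait registry used to recognise trait columns in wide
#'   input; see [trait_registry()].
#' @param na strings treated as missing (default `"NA"` and empty).
#' @return a plot-record tibble (see [as_plot_records()]).
#' @export
read_plot_table <- function(path, column_map = NULL,
                            registry = trait_registry(),
                            na = c("NA", "")) {
  if (is.character(column_map) && length(column_map) == 1 &&
      file.exists(column_map)) {
    column_map <- unlist(yaml::read_yaml(column_map))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na,
                         check.names = FALSE, colClasses = "character")
  raw <- tibble::as_tibble(raw)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("genotype", "year", "location", "management")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) stop("input lacks mandatory column(s): ",
                         paste(miss, collapse = ", "))

  long <- all(c("trait", "value") %in% names(raw))
  if (!long) {
    trait_cols <- intersect(names(raw), registry$trait)
    if (!length(trait_cols)) stop("no trait columns recognised; ",
                                  "extend the registry or supply a column_map")
    id_cols <- setdiff(names(raw), trait_cols)
    raw <- tidyr::pivot_longer(raw, cols = dplyr::all_of(trait_cols),
                               names_to = "trait", values_to = "value")
    raw <- raw[!is.na(raw$value), ]
  }
  raw$value <- parse_numeric(raw$value, "value")
  for (col in c("year", "release_year", "replicate", "row", "col")) {
    if (col %in% names(raw)) raw[[col]] <- parse_numeric(raw[[col]], col)
  }
  as_plot_records(raw)
}

# strict numeric parsing: malformed cells -> NA with one warning per column
parse_numeric <- function(x, what) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warning(sum(bad), " malformed numeric cell(s) in '", what,
            "' set to NA (e.g. \"", x[bad][1], "\")", call. = FALSE)
  }
  out
}

#' Write a plot-record table to CSV
#'
#' Writes the canonical long format; [read_plot_table()] round-trips it.
#' @param records plot-record tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(records, path) {
  records <- as_plot_records(records)
  utils::write.csv(records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate plot records against the schema invariants
#'
#' Checks, without mutating the input: trait membership in the registry,
#' disease scores within \[0, 100\], replicate in 1..3, management label
#' among the observed nine, missing mandatory fields, and duplicated
#' (genotype, condition, replicate, trait) keys.
#'
#' @param records plot-record tibble.
#' @param registry trait registry; see [trait_registry()].
#' @return tibble with columns `rule` and `n` (offending record counts).
#' @export
validate_records <- function(records, registry = trait_registry()) {
  records <- as_plot_records(records)
  dis <- registry$trait[registry$is_disease]
  is_dis <- records$trait %in% dis
  key <- paste(records$genotype,
               condition_key(records$year, records$location,
                             records$management),
               records$replicate, records$trait, sep = "\r")
  rules <- c(
    unknown_trait = sum(!records$trait %in% registry$trait),
    disease_out_of_range = sum(is_dis & !is.na(records$value) &
                                 (records$value < 0 | records$value > 100)),
    replicate_out_of_range = sum(!is.na(records$replicate) &
                                   !records$replicate %in% 1:3),
    unknown_management = sum(!records$management %in% OBSERVED_MANAGEMENTS),
    missing_mandatory = sum(is.na(records$genotype) | is.na(records$year) |
                              is.na(records$location) |
                              is.na(records$management)),
    duplicate_observation = sum(duplicated(key))
  )
  tibble::tibble(rule = names(rules), n = unname(rules))
}

#' Read cultivar metadata from CSV
#'
#' @param path CSV with (possibly renamed) columns `genotype`, `name`,
#'   `release_year`.
#' @param column_map optional named vector as in [read_plot_table()].
#' @param release_span permitted span of release years, default 1963-2016.
#' @return tibble `genotype`, `name`, `release_year`.
#' @export
read_cultivar_meta <- function(path, column_map = NULL,
                               release_span = c(1963L, 2016L)) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           na.strings = c("NA", "")))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  miss <- setdiff(c("genotype", "release_year"), names(raw))
  if (length(miss)) stop("cultivar metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"name" %in% names(raw)) raw$name <- raw$genotype
  raw$genotype <- as.character(raw$genotype)
  raw$release_year <- as.integer(raw$release_year)
  if (anyDuplicated(raw$genotype)) stop("duplicated genotype ids in metadata")
  out_span <- !is.na(raw$release_year) &
    (raw$release_year < release_span[1] | raw$release_year > release_span[2])
  if (any(out_span)) {
    warning(sum(out_span), " release year(s) outside the declared span ",
            release_span[1], "-", release_span[2], call. = FALSE)
  }
  raw[, c("genotype", "name", "release_year")]
}
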