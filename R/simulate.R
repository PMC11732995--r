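#' Specify one simulated trait
#'
#' A trait is generated per plot as
#' `grand_mean + g_i + bp_slope * (release_year - midpoint) + e_condition +
#'  management_shift + gxe_ic + row_r + col_c + residual`,
#' with `g_i ~ N(0, genotype_sd)`, condition effects `~ N(0, env_sd)`,
#' genotype-by-condition interactions `gxe_ic ~ N(0, sd_i)` where `sd_i` is
#' drawn per genotype uniformly from `gxe_sd_range` (the genotype's true
#' instability), and independent row, column and residual noise.
#'
#' @param grand_mean trait mean in trait units.
#' @param bp_slope true breeding-progress slope, trait units per release year.
#' @param genotype_sd,env_sd,row_sd,col_sd,residual_sd component standard
#'   deviations (trait units, all >= 0).
#' @param gxe_sd_range length-2 range from which each genotype's interaction
#'   sd is drawn.
#' @param management_shifts named numeric of additive shifts per treatment
#'   level (names among `LN`, `NF`, `IR`, `RO`; unnamed levels shift 0; the
#'   reference levels `HN`, `WF`, `RF` always shift 0).
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(grand_mean, bp_slope = 0, genotype_sd = 0, env_sd = 0,
                       gxe_sd_range = c(0, 0), row_sd = 0, col_sd = 0,
                       residual_sd = 0, management_shifts = numeric()) {
  stopifnot(length(gxe_sd_range) == 2, all(gxe_sd_range >= 0),
            gxe_sd_range[1] <= gxe_sd_range[2],
            genotype_sd >= 0, env_sd >= 0, row_sd >= 0, col_sd >= 0,
            residual_sd >= 0)
  structure(list(grand_mean = grand_mean, bp_slope = bp_slope,
                 genotype_sd = genotype_sd, env_sd = env_sd,
                 gxe_sd_range = as.numeric(gxe_sd_range),
                 row_sd = row_sd, col_sd = col_sd,
                 residual_sd = residual_sd,
                 management_shifts = management_shifts),
            class = "trait_spec")
}

#' Specify one simulated disease score
#'
#' Disease scores are generated on a latent Gaussian scale --
#' `baseline + resistance_trend * (release_year - midpoint) + g_i +
#'  e_condition + noise` -- then clamped to the 0-100 scoring scale.
#'
#' @param baseline latent mean infection (% area).
#' @param resistance_trend latent slope per release year (negative when
#'   modern cultivars are more resistant).
#' @param genotype_sd sd of genotype resistance effects.
#' @param env_sd sd of condition (epidemic pressure) effects.
#' @param overdispersion residual latent sd per plot.
#' @return a `disease_spec` list.
#' @export
disease_spec <- function(baseline = 12, resistance_trend = -0.15,
                         genotype_sd = 4, env_sd = 6, overdispersion = 8) {
  stopifnot(genotype_sd >= 0, env_sd >= 0, overdispersion >= 0)
  structure(list(baseline = baseline, resistance_trend = resistance_trend,
                 genotype_sd = genotype_sd, env_sd = env_sd,
                 overdispersion = overdispersion),
            class = "disease_spec")
}

# expand component-level shifts (LN, NF, IR, RO) into per-label shifts
management_shift_for <- function(labels, shifts) {
  if (!length(shifts)) return(stats::setNames(numeric(length(labels)), labels))
  comp <- parse_management(labels, observed_only = FALSE)
  out <- numeric(length(labels))
  for (lev in names(shifts)) {
    hit <- comp$nitrogen == lev | comp$fungicide == lev | comp$water == lev
    out[hit] <- out[hit] + shifts[[lev]]
  }
  stats::setNames(out, labels)
}

#' Default trait specifications for a winter-wheat MET
#'
#' Seven agronomic traits with means and noise magnitudes chosen so that
#' simulated values fall inside the observed ranges of real German
#' winter-wheat trials (e.g. whole-plot grain yield within 0-141.6 dt/ha)
#' and with a grain-yield breeding-progress slope of 0.37 dt/ha per release
#' year, the magnitude reported for long-term German winter-wheat panels.
#' @return named list of [trait_spec()] objects keyed by registry trait name.
#' @export
default_trait_specs <- function() {
  list(
    Seedyield = trait_spec(80, bp_slope = 0.37, genotype_sd = 6, env_sd = 10,
                           gxe_sd_range = c(0.5, 3), row_sd = 1.5,
                           col_sd = 1.5, residual_sd = 3,
                           management_shifts = c(LN = -10, NF = -6,
                                                 IR = 5, RO = -15)),
    TGW = trait_spec(45, bp_slope = 0.03, genotype_sd = 3, env_sd = 2.5,
                     gxe_sd_range = c(0.2, 1.2), row_sd = 0.4, col_sd = 0.4,
                     residual_sd = 1.2,
                     management_shifts = c(LN = -1, NF = -1.5, RO = -2)),
    Harvest_Index_bio = trait_spec(0.5, bp_slope = 0.0015, genotype_sd = 0.03,
                                   env_sd = 0.02,
                                   gxe_sd_range = c(0.003, 0.015),
                                   row_sd = 0.005, col_sd = 0.005,
                                   residual_sd = 0.01,
                                   management_shifts = c(LN = -0.01,
                                                         RO = -0.03)),
    Straw = trait_spec(80, bp_slope = -0.05, genotype_sd = 6, env_sd = 10,
                       gxe_sd_range = c(0.5, 3), row_sd = 1.5, col_sd = 1.5,
                       residual_sd = 4,
                       management_shifts = c(LN = -8, RO = -12)),
    Grain_per_spike_bio = trait_spec(30, bp_slope = 0.08, genotype_sd = 3,
                                     env_sd = 3, gxe_sd_range = c(0.3, 1.5),
                                     row_sd = 0.5, col_sd = 0.5,
                                     residual_sd = 1.5,
                                     management_shifts = c(LN = -2)),
    Spike_number_bio = trait_spec(450, bp_slope = -0.5, genotype_sd = 40,
                                  env_sd = 60, gxe_sd_range = c(5, 30),
                                  row_sd = 10, col_sd = 10, residual_sd = 25,
                                  management_shifts = c(LN = -40, RO = -60)),
    Crude_protein = trait_spec(13, bp_slope = -0.025, genotype_sd = 1,
                               env_sd = 1, gxe_sd_range = c(0.1, 0.6),
                               row_sd = 0.15, col_sd = 0.15,
                               residual_sd = 0.4,
                               management_shifts = c(LN = -1.5, NF = 0.2))
  )
}

#' Default disease specifications
#' @return named list of [disease_spec()] objects for the six disease scores.
#' @export
default_disease_specs <- function() {
  list(
    Stripe_rust = disease_spec(10, -0.18, 5, 7, 8),
    Septoria = disease_spec(15, -0.10, 4, 6, 8),
    Powdery_mildew = disease_spec(8, -0.12, 4, 5, 6),
    Leaf_rust = disease_spec(10, -0.15, 4, 6, 7),
    DTR = disease_spec(6, -0.05, 3, 4, 5),
    Fusarium = disease_spec(3, -0.03, 1.5, 2, 2.5)
  )
}

#' Configure a synthetic MET
#'
#' @param n_genotypes number of cultivars in the panel.
#' @param release_span integer `c(first, last)` release year.
#' @param conditions tibble of growing conditions with columns `year`,
#'   `location`, `management` and optionally `replicates` (per-condition
#'   override) and `genotype_set` (`"all"` or `"subset"` for a reduced
#'   phase-II panel).
#' @param replicates default replicates per condition.
#' @param layout `c(n_rows, n_cols)` of the per-condition field grid, or
#'   `NULL` to choose a near-square grid holding all plots.
#' @param trait_specs named list of [trait_spec()]; see
#'   [default_trait_specs()].
#' @param disease_specs named list of [disease_spec()]; empty list to skip
#'   diseases.
#' @param subset_size size of the reduced panel used by conditions marked
#'   `genotype_set = "subset"`.
#' @param seed integer seed making the draw reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 60,
                       release_span = c(1963L, 2016L),
                       conditions = NULL,
                       replicates = 2L,
                       layout = NULL,
                       trait_specs = default_trait_specs(),
                       disease_specs = default_disease_specs(),
                       subset_size = NULL,
                       seed = 1L) {
  if (is.null(conditions)) {
    conditions <- tidyr::expand_grid(year = 2015:2017,
                                     location = c("GGE", "HAN"),
                                     management = c("HN_WF_RF", "LN_NF_RF"))
  }
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("year", "location", "management") %in% names(conditions)),
            replicates >= 1, n_genotypes >= 2)
  parse_management(unique(conditions$management))  # reject unknown labels
  if (!"replicates" %in% names(conditions)) {
    conditions$replicates <- as.integer(replicates)
  }
  if (!"genotype_set" %in% names(conditions)) conditions$genotype_set <- "all"
  if (!is.null(layout)) {
    if (prod(layout) < n_genotypes * max(conditions$replicates)) {
      stop("layout too small for ", n_genotypes * max(conditions$replicates),
           " plots")
    }
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 release_span = as.integer(release_span),
                 conditions = conditions,
                 replicates = as.integer(replicates),
                 layout = layout,
                 trait_specs = trait_specs,
                 disease_specs = disease_specs,
                 subset_size = subset_size,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Reference trial-network design
#'
#' A design emulating the structure of the German winter-wheat MET network:
#' six harvest years (2015-2020) by six locations masked to 29 environments,
#' nine managements (the nitrogen x fungicide cross rain-fed everywhere;
#' the same cross irrigated only in Gross Gerau in 2015, 2018 and 2019,
#' where only HN_WF stays rain-fed alongside; one HN_WF rain-out-shelter
#' treatment only in Kiel in 2016, 2017 and 2019), a 220-cultivar phase-I
#' panel (2015-2017) with a 52-cultivar phase-II subset (2018-2020), two
#' replicates everywhere except three for Kiel rain-fed conditions.
#'
#' @param n_genotypes phase-I panel size, default 220.
#' @param subset_size phase-II panel size, default 52.
#' @param seed simulation seed.
#' @inheritParams sim_config
#' @return a `sim_config`.
#' @export
met_design_reference <- function(n_genotypes = 220L, subset_size = 52L,
                                 trait_specs = default_trait_specs(),
                                 disease_specs = default_disease_specs(),
                                 seed = 1L) {
  locs <- c("GGE", "HAN", "KAL", "KIE", "QLB", "RHH")
  env <- tidyr::expand_grid(year = 2015:2020, location = locs)
  # mask the full 6x6 grid down to the 29 realised environments
  dropped <- paste(c(2017, 2018, 2018, 2018, 2020, 2020, 2020),
                   c("RHH", "GGE", "KAL", "RHH", "GGE", "QLB", "RHH"))
  env <- env[!paste(env$year, env$location) %in% dropped, ]
  stopifnot(nrow(env) == 29)

  rf_cross <- c("HN_WF_RF", "HN_NF_RF", "LN_WF_RF", "LN_NF_RF")
  rows <- lapply(seq_len(nrow(env)), function(i) {
    y <- env$year[i]; l <- env$location[i]
    if (l == "GGE" && y %in% c(2015, 2018, 2019)) {
      mg <- c("HN_WF_IR", "HN_NF_IR", "LN_WF_IR", "LN_NF_IR", "HN_WF_RF")
    } else {
      mg <- rf_cross
      if (l == "KIE" && y %in% c(2016, 2017, 2019)) mg <- c(mg, "HN_WF_RO")
    }
    tibble::tibble(year = y, location = l, management = mg)
  })
  conditions <- dplyr::bind_rows(rows)
  conditions$replicates <- ifelse(conditions$location == "KIE" &
                                    grepl("_RF$", conditions$management),
                                  3L, 2L)
  conditions$genotype_set <- ifelse(conditions$year >= 2018, "subset", "all")
  sim_config(n_genotypes = n_genotypes, release_span = c(1963L, 2016L),
             conditions = conditions, replicates = 2L,
             trait_specs = trait_specs, disease_specs = disease_specs,
             subset_size = subset_size, seed = seed)
}

#' Balanced validation-subset design
#'
#' The more balanced subset used throughout the worked analyses: three
#' phase-I years (2015-2017), five locations (GGE, HAN, KAL, KIE, QLB) and
#' the three rain-fed managements HN_WF_RF, HN_NF_RF and LN_NF_RF -- 45
#' growing conditions, 220 genotypes, two replicates.
#' @inheritParams met_design_reference
#' @return a `sim_config`.
#' @export
met_design_validation <- function(n_genotypes = 220L,
                                  trait_specs = default_trait_specs(),
                                  disease_specs = default_disease_specs(),
                                  seed = 1L) {
  conditions <- tidyr::expand_grid(
    year = 2015:2017,
    location = c("GGE", "HAN", "KAL", "KIE", "QLB"),
    management = c("HN_WF_RF", "HN_NF_RF", "LN_NF_RF"))
  sim_config(n_genotypes = n_genotypes, release_span = c(1963L, 2013L),
             conditions = conditions, replicates = 2L,
             trait_specs = trait_specs, disease_specs = disease_specs,
             seed = seed)
}

#' Simulate a plot-level MET with known ground truth
#'
#' Draws genotype effects, per-condition environment effects, genotype-wise
#' interaction standard deviations, row/column field gradients and residual
#' noise per the configuration, lays plots out on a per-condition grid with
#' genotype placement randomised within each replicate block, and returns
#' both the plot records and the generating truth.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return list with elements
#'   `plots` (plot-record tibble, see [as_plot_records()]),
#'   `truth` (list: `genotypes` tibble with release years and per-trait
#'   columns `g_<trait>` and `gxe_sd_<trait>`; `conditions` tibble with
#'   per-trait environment effects `e_<trait>`; `bp_slope` named vector;
#'   `field` list of per-condition row/column effects), and
#'   `config`.
#' @examples
#' sim <- simulate_met(sim_config(n_genotypes = 10, seed = 42))
#' head(sim$plots)
#' @export
simulate_met <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  ng <- config$n_genotypes
  genotypes <- sprintf("G%04d", seq_len(ng))
  span <- config$release_span
  release <- sort(sample(seq(span[1], span[2]), ng, replace = TRUE))
  mid <- mean(span)
  conds <- config$conditions
  conds$condition <- condition_key(conds$year, conds$location,
                                   conds$management)

  specs <- config$trait_specs
  dspecs <- config$disease_specs
  truth_g <- tibble::tibble(genotype = genotypes, release_year = release)
  for (tr in names(specs)) {
    truth_g[[paste0("g_", tr)]] <- stats::rnorm(ng, 0, specs[[tr]]$genotype_sd)
    truth_g[[paste0("gxe_sd_", tr)]] <-
      stats::runif(ng, specs[[tr]]$gxe_sd_range[1],
                   specs[[tr]]$gxe_sd_range[2])
  }
  for (dz in names(dspecs)) {
    truth_g[[paste0("g_", dz)]] <- stats::rnorm(ng, 0, dspecs[[dz]]$genotype_sd)
  }
  truth_c <- conds[, c("condition", "year", "location", "management")]
  for (tr in names(specs)) {
    truth_c[[paste0("e_", tr)]] <- stats::rnorm(nrow(conds), 0,
                                                specs[[tr]]$env_sd)
  }
  for (dz in names(dspecs)) {
    truth_c[[paste0("e_", dz)]] <- stats::rnorm(nrow(conds), 0,
                                                dspecs[[dz]]$env_sd)
  }
  shift_tabs <- lapply(specs, function(sp) {
    management_shift_for(unique(conds$management), sp$management_shifts)
  })

  # phase-II style reduced panel: deterministic-from-seed subset
  subset_idx <- if (!is.null(config$subset_size)) {
    sort(sample(ng, config$subset_size))
  } else seq_len(ng)

  field <- list()
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    gset <- if (identical(conds$genotype_set[i], "subset")) subset_idx
            else seq_len(ng)
    reps <- conds$replicates[i]
    n_plots <- length(gset) * reps
    layout <- config$layout
    if (is.null(layout)) {
      nr <- ceiling(sqrt(n_plots))
      layout <- c(nr, ceiling(n_plots / nr))
    }
    row_eff <- stats::rnorm(layout[1], 0, 1)
    col_eff <- stats::rnorm(layout[2], 0, 1)
    field[[conds$condition[i]]] <- list(row = row_eff, col = col_eff)
    # randomised placement within each replicate block
    order_g <- unlist(lapply(seq_len(reps), function(r) sample(gset)))
    plot_no <- seq_len(n_plots)
    prow <- ((plot_no - 1) %/% layout[2]) + 1L
    pcol <- ((plot_no - 1) %% layout[2]) + 1L
    base <- tibble::tibble(
      genotype = genotypes[order_g],
      release_year = release[order_g],
      year = conds$year[i], location = conds$location[i],
      management = conds$management[i],
      replicate = rep(seq_len(reps), each = length(gset)),
      row = prow, col = pcol)
    vals <- list()
    for (tr in names(specs)) {
      sp <- specs[[tr]]
      gxe <- stats::rnorm(length(gset), 0,
                          truth_g[[paste0("gxe_sd_", tr)]][gset])
      names(gxe) <- genotypes[gset]
      vals[[tr]] <- sp$grand_mean +
        truth_g[[paste0("g_", tr)]][order_g] +
        sp$bp_slope * (release[order_g] - mid) +
        truth_c[[paste0("e_", tr)]][i] +
        shift_tabs[[tr]][[conds$management[i]]] +
        gxe[base$genotype] +
        sp$row_sd * row_eff[prow] + sp$col_sd * col_eff[pcol] +
        stats::rnorm(n_plots, 0, sp$residual_sd)
    }
    for (dz in names(dspecs)) {
      sp <- dspecs[[dz]]
      latent <- sp$baseline +
        sp$resistance_trend * (release[order_g] - mid) +
        truth_g[[paste0("g_", dz)]][order_g] +
        truth_c[[paste0("e_", dz)]][i] +
        stats::rnorm(n_plots, 0, sp$overdispersion)
      vals[[dz]] <- pmin(pmax(latent, 0), 100)
    }
    out[[i]] <- dplyr::bind_cols(
      base[rep(seq_len(n_plots), times = length(vals)), ],
      tibble::tibble(trait = rep(names(vals), each = n_plots),
                     value = unlist(vals, use.names = FALSE)))
  }
  plots <- as_plot_records(dplyr::bind_rows(out))
  truth <- list(genotypes = truth_g, conditions = truth_c,
                bp_slope = vapply(specs, function(s) s$bp_slope, numeric(1)),
                subset = genotypes[subset_idx], field = field)
  structure(list(plots = plots, truth = truth, config = config),
            class = "met_sim")
}
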