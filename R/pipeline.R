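#' Configure an end-to-end pipeline run
#'
#' @param out_dir directory for output CSVs, or `NULL` to return results
#'   only.
#' @param seed integer seed for the simulation stage.
#' @param sim a [sim_config()] used when no `input` file is given; default
#'   [met_design_validation()] with `seed`.
#' @param input optional plot-level CSV (read with [read_plot_table()])
#'   replacing the simulation stage.
#' @param meta optional cultivar metadata (tibble or CSV path); required
#'   with `input`, derived from the simulation truth otherwise.
#' @param column_map passed to [read_plot_table()] for `input`.
#' @param analysis_traits traits carried through BLUE estimation; default
#'   the seven default simulated traits.
#' @param response response trait of the BP and SI decompositions.
#' @param bp_regressors,si_regressors component traits of the two
#'   decompositions.
#' @param consistency_traits traits for the consistency stage.
#' @param groupings list of `fixed_factors` vectors for [group_pairs()];
#'   the pooled grouping is always included.
#' @param si_names stability indices to decompose; default all nine.
#' @param compare_table optional genotype x trait table (or CSV path) of
#'   external (e.g. crop-model) output for the correlation comparison.
#' @param stages named logical toggles: `qc`, `blues`, `consistency`,
#'   `progress`, `stability`, `compare`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L, sim = NULL,
                            input = NULL, meta = NULL, column_map = NULL,
                            analysis_traits = names(default_trait_specs()),
                            response = "Seedyield",
                            bp_regressors = c("TGW", "Harvest_Index_bio",
                                              "Straw",
                                              "Grain_per_spike_bio",
                                              "Spike_number_bio"),
                            si_regressors = c("TGW", "Harvest_Index_bio",
                                              "Straw",
                                              "Grain_per_spike_bio",
                                              "Spike_number_bio",
                                              "Crude_protein"),
                            consistency_traits = "Seedyield",
                            groupings = list("management", "location",
                                             "year"),
                            si_names = si_direction()$index,
                            compare_table = NULL,
                            stages = c(qc = TRUE, blues = TRUE,
                                       consistency = TRUE, progress = TRUE,
                                       stability = TRUE, compare = TRUE)) {
  if (is.null(sim) && is.null(input)) {
    sim <- met_design_validation(seed = seed)
  }
  defaults <- c(qc = TRUE, blues = TRUE, consistency = TRUE,
                progress = TRUE, stability = TRUE, compare = TRUE)
  defaults[names(stages)] <- stages
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input = input, meta = meta, column_map = column_map,
                 analysis_traits = analysis_traits, response = response,
                 bp_regressors = bp_regressors,
                 si_regressors = si_regressors,
                 consistency_traits = consistency_traits,
                 groupings = groupings, si_names = si_names,
                 compare_table = compare_table, stages = defaults),
            class = "pipeline_config")
}

# CSV writer with a provenance comment header; read back with
# utils::read.csv(comment.char = "#")
write_stage_csv <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# metgxe ", as.character(utils::packageVersion("metgxe"))),
    paste0("# seed: ", seed),
    paste0("# config: ", config_hash)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "NA",
                     qmethod = "double")
  path
}

#' Run the full MET analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic simulation or CSV
#' input), quality control, per-condition BLUE estimation, and the four
#' analyses -- trait consistency, breeding-progress decomposition,
#' stability decomposition and (when an external table is supplied)
#' correlation-structure comparison. Each enabled stage's tables are
#' returned and, when `out_dir` is set, written as CSVs carrying a
#' provenance header (package version, seed, configuration hash).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a named list of stage results: `plots`, `meta`,
#'   `qc_report`, `blues`, `consistency`, `bp`, `bp_models`,
#'   `bp_importance`, `stability`, `si_models`, `si_importance`,
#'   `comparison`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[metgxe] ", ...)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  res <- list(files = character())
  emit <- function(df, name) {
    if (is.null(config$out_dir)) return(invisible())
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    write_stage_csv(df, p, config$seed, cfg_hash)
    res$files <<- c(res$files, p)
  }

  # -- data ---------------------------------------------------------------
  if (!is.null(config$input)) {
    say("reading ", config$input)
    plots <- read_plot_table(config$input, config$column_map)
    meta <- config$meta
    if (is.character(meta)) meta <- read_cultivar_meta(meta)
    if (is.null(meta)) {
      meta <- dplyr::distinct(plots[!is.na(plots$release_year),
                                    c("genotype", "release_year")])
    }
  } else {
    say("simulating MET (", config$sim$n_genotypes, " genotypes, ",
        nrow(config$sim$conditions), " conditions)")
    sim <- simulate_met(config$sim, seed = config$seed)
    plots <- sim$plots
    meta <- sim$truth$genotypes[, c("genotype", "release_year")]
    res$truth <- sim$truth
  }
  res$plots <- plots
  res$meta <- meta

  # -- qc -----------------------------------------------------------------
  if (config$stages[["qc"]]) {
    say("quality control")
    qc <- qc_pipeline(plots)
    plots <- qc$records
    res$qc_report <- qc$report
    emit(qc$report, "qc_report")
  }

  # -- blues --------------------------------------------------------------
  if (!config$stages[["blues"]]) {
    return(invisible(res))
  }
  traits <- intersect(c(config$analysis_traits,
                        if ("TFI" %in% plots$trait) "TFI"),
                      unique(plots$trait))
  say("BLUE estimation for ", length(traits), " traits")
  blues <- build_blue_table(plots, traits = traits)
  res$blues <- blues
  emit(blues, "blues")

  # -- consistency --------------------------------------------------------
  if (config$stages[["consistency"]]) {
    say("trait consistency")
    pair_list <- list(); summ_list <- list()
    for (tr in config$consistency_traits) {
      pairs <- pairwise_consistency(blues, tr)
      pair_list[[tr]] <- pairs
      groupings <- c(list(character()), config$groupings)
      for (gf in groupings) {
        lab <- if (!length(gf)) "all" else paste(gf, collapse = "-")
        sm <- summarise_consistency(group_pairs(pairs, gf))
        sm$trait <- tr
        sm$grouping <- lab
        sm$anova_p <- attr(sm, "anova_p")
        summ_list[[paste(tr, lab)]] <- sm
      }
    }
    res$consistency <- list(pairs = dplyr::bind_rows(pair_list),
                            summary = dplyr::bind_rows(summ_list))
    emit(res$consistency$pairs, "consistency_pairs")
    emit(res$consistency$summary, "consistency_summary")
  }

  # -- progress -----------------------------------------------------------
  if (config$stages[["progress"]]) {
    say("breeding progress")
    bp_traits <- intersect(c(config$response, config$bp_regressors), traits)
    bp <- bp_table(blues, meta, traits = bp_traits)
    res$bp <- bp
    emit(bp, "bp")
    models <- tryCatch(
      bp_regression(bp, response = config$response,
                    regressors = intersect(config$bp_regressors, bp$trait),
                    grouping = "management"),
      error = function(e) {
        warning("BP regression skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(models)) {
      res$bp_models <- models
      emit(models, "bp_regression")
      wide <- tidyr::pivot_wider(bp[, c("condition", "trait", "bp")],
                                 names_from = "trait", values_from = "bp")
      need <- intersect(c(config$response, config$bp_regressors),
                        names(wide))
      wide <- wide[stats::complete.cases(wide[, need]), ]
      if (nrow(wide) > length(need) + 1) {
        imp <- lmg(wide[[config$response]],
                   wide[, setdiff(need, config$response)])
        res$bp_importance <- stacked_importance(list(all = imp))
        emit(res$bp_importance, "bp_importance")
      }
    }
  }

  # -- stability ----------------------------------------------------------
  if (config$stages[["stability"]]) {
    say("stability indices")
    st_traits <- intersect(c(config$response, config$si_regressors), traits)
    tabs <- list(); st_rows <- list()
    for (tr in st_traits) {
      m <- tryCatch(suppressMessages(build_trait_matrix(blues, tr)),
                    error = function(e) NULL)
      if (is.null(m)) next
      st <- stability_indices(m)
      tabs[[tr]] <- st
      st$trait <- tr
      st_rows[[tr]] <- st
    }
    res$stability <- dplyr::bind_rows(st_rows)
    emit(res$stability, "stability")
    tfi <- if ("TFI" %in% blues$trait) {
      tfi_regressor(blues, genotypes = tabs[[1]]$genotype)
    } else NULL
    if (length(tabs) >= 2 && config$response %in% names(tabs)) {
      si_models <- list(); si_imp <- list()
      for (si in config$si_names) {
        fitted <- tryCatch(
          si_regression(tabs, si, tfi = tfi, response = config$response),
          error = function(e) NULL)
        if (is.null(fitted)) next
        si_models[[si]] <- fitted
        # importance on the same design matrix
        common <- Reduce(intersect, lapply(tabs, function(t) t$genotype))
        if (!is.null(tfi)) common <- intersect(common,
                                               names(tfi)[!is.na(tfi)])
        d <- data.frame(row.names = common)
        for (tr in names(tabs)) {
          d[[tr]] <- tabs[[tr]][[si]][match(common, tabs[[tr]]$genotype)]
        }
        if (!is.null(tfi)) d$TFI <- unname(tfi[common])
        d <- d[stats::complete.cases(d), ]
        Xc <- d[, setdiff(names(d), config$response), drop = FALSE]
        Xc <- Xc[, vapply(Xc, function(v) stats::sd(v) > 0, TRUE),
                 drop = FALSE]
        imp <- tryCatch(lmg(d[[config$response]], Xc),
                        error = function(e) NULL)
        if (!is.null(imp)) si_imp[[si]] <- imp
      }
      res$si_models <- dplyr::bind_rows(si_models)
      emit(res$si_models, "si_regression")
      res$si_importance <- stacked_importance(si_imp)
      emit(res$si_importance, "si_importance")
    }
  }

  # -- compare ------------------------------------------------------------
  if (config$stages[["compare"]] && !is.null(config$compare_table)) {
    say("correlation comparison")
    ext <- config$compare_table
    if (is.character(ext)) {
      ext <- utils::read.csv(ext, stringsAsFactors = FALSE)
    }
    shared <- intersect(traits, names(ext))
    # genotype means across conditions feed the field correlations
    gm <- dplyr::summarise(
      dplyr::group_by(blues[blues$trait %in% shared, ], .data$genotype,
                      .data$trait),
      blue = mean(.data$blue), .groups = "drop")
    field_wide <- tidyr::pivot_wider(gm, names_from = "trait",
                                     values_from = "blue")
    res$comparison <- compare_correlations(
      corr_table(field_wide, traits = shared),
      corr_table(ext, traits = shared))
    emit(res$comparison, "comparison")
  }
  say("done")
  invisible(res)
}
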