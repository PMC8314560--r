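# End-to-end orchestration: simulate -> mask -> impute -> mediate ->
# cluster -> report, under one master seed, with a manifest that makes
# every run self-describing and reproducible.

#' Pipeline configuration
#'
#' @param scenario a [scenario_config()] / [scenario_preset()] name or
#'   object, or `NULL` when `cohort_path` is given.
#' @param cohort_path path of an existing cohort CSV (alternative to
#'   `scenario`).
#' @param m number of imputations.
#' @param iterations chained-equation iterations.
#' @param mediate a [mediate_config()]; its seed is overridden by the
#'   master seed fan-out.
#' @param outcomes outcomes to analyse.
#' @param out_dir run directory for all artifacts.
#' @param master_seed explicit integer master seed (wall-clock seeding is
#'   deliberately not supported).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "null", cohort_path = NULL,
                            m = 31L, iterations = 10L,
                            mediate = mediate_config(),
                            outcomes = cohort_outcomes,
                            out_dir = tempfile("rfmediate_run_"),
                            master_seed = 1L) {
  if (is.character(scenario))
    scenario <- scenario_preset(scenario, seed = derive_seed(master_seed, 1L))
  if (!is.null(scenario)) validate_scenario_config(scenario)
  if (is.null(scenario) && is.null(cohort_path))
    stopf("either a scenario or a cohort_path is required")
  structure(list(scenario = scenario, cohort_path = cohort_path,
                 m = as.integer(m), iterations = as.integer(iterations),
                 mediate = mediate, outcomes = outcomes, out_dir = out_dir,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full mediation pipeline
#'
#' Stages: (1) simulate or load the cohort; (2) inject missingness
#' (simulated cohorts only); (3) chained-equations imputation; (4)
#' random-forest mediation analysis; (5) clustering, heatmap and report.
#' All stage outputs are written under one run directory; a
#' `manifest.json` records the config, the derived stage seeds, and an md5
#' checksum per numeric artifact, so a rerun with the same config can be
#' verified checksum-identical. Stage seeds fan out from the master seed by
#' fixed offsets.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the fitted `rf_mediation`, the stage
#'   artifact paths and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
            name, conditionMessage(e), cfg$out_dir))
    res
  }

  cohort <- stage("simulate", {
    if (!is.null(cfg$cohort_path)) read_cohort(cfg$cohort_path)
    else {
      sc <- cfg$scenario
      co <- simulate_cohort(sc)
      co <- inject_missingness(co, sc)
      paths$cohort <- file.path(cfg$out_dir, "cohort.csv")
      write_cohort(co, paths$cohort)
      co
    }
  })

  stack <- stage("impute", {
    st <- impute_outcomes(cohort, m = cfg$m, iterations = cfg$iterations,
                          seed = derive_seed(cfg$master_seed, 20L))
    paths$stack <- file.path(cfg$out_dir, "stack")
    write_imputed_stack(st, paths$stack)
    st
  })

  fit <- stage("mediate", {
    mcfg <- cfg$mediate
    mcfg$seed <- derive_seed(cfg$master_seed, 30L)
    f <- mediate_rf(stack, outcomes = cfg$outcomes, config = mcfg)
    paths$results <- file.path(cfg$out_dir, "results.json")
    write_mediation_json(f, paths$results)
    f
  })

  cr <- stage("cluster", {
    fm <- frequency_matrix(fit)
    paths$frequencies <- file.path(cfg$out_dir, "frequency_matrix.csv")
    utils::write.csv(as.data.frame(fm), paths$frequencies, row.names = TRUE)
    if (nrow(fm) >= 2 && ncol(fm) >= 2) {
      paths$heatmap <- file.path(cfg$out_dir, "heatmap.png")
      render_heatmap(fm, panel = fit$panel, path = paths$heatmap,
                     n_bootstrap = fit$config$n_boot_freq)
      read_heatmap_sidecar(paths$heatmap)  # round-trip check
    } else NULL
  })

  stage("report", {
    paths$report <- file.path(cfg$out_dir, "report.md")
    report_mediation(fit, paths$report, heatmap = paths$heatmap)
  })

  manifest <- list(
    master_seed = cfg$master_seed,
    stage_seeds = list(simulate = if (!is.null(cfg$scenario)) cfg$scenario$seed,
                       impute = derive_seed(cfg$master_seed, 20L),
                       mediate = derive_seed(cfg$master_seed, 30L)),
    m = cfg$m, iterations = cfg$iterations,
    outcomes = cfg$outcomes,
    scenario = if (!is.null(cfg$scenario))
      c(unclass(cfg$scenario), list(name = attr(cfg$scenario, "scenario"))),
    stages = names(paths),
    checksums = as.list(tools::md5sum(unlist(paths[c("cohort", "results",
                                                     "frequencies")])))
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(fit = fit, paths = paths, manifest = manifest,
                 clustering = cr))
}

#' Serialize mediation results as JSON
#'
#' One document per analysis: per outcome the corrected/apparent R-squared
#' for every model variant, the fold-increases, the significance-frequency
#' vectors and the mediation flag, plus the configuration.
#'
#' @param fit an `rf_mediation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mediation_json <- function(fit, path) {
  out <- list(
    config = fit$config[c("n_boot_r2", "n_boot_freq", "n_permutations",
                          "alpha", "threshold_frac", "pool", "seed")],
    m = fit$m,
    outcomes = lapply(fit$outcomes, function(r) list(
      r2 = lapply(r$r2, function(v) list(corrected = v$corrected,
                                         apparent = v$apparent)),
      folds = r$folds,
      intervention_frequency = as.list(r$intervention_frequency),
      max_cpg_frequency = r$max_cpg_frequency,
      mediation_flag = r$mediation_flag,
      frequencies = lapply(r$frequencies, as.list))),
    skipped = fit$skipped)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
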