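#' Scenario configuration for the synthetic-cohort generator
#'
#' Describes a treatment -> mediator-CpG -> outcome data-generating process
#' with baseline-covariate confounding and missing-at-random outcome
#' missingness. Arm shifts at mediator sites are additive on the logit-beta
#' scale so generated beta-values always stay inside (0, 1).
#'
#' @param n_per_arm integer pair: patients in the early-PN and late-PN arm.
#' @param n_cpg number of CpG-sites on the panel (default 37).
#' @param n_mediators number of panel sites that truly mediate (<= `n_cpg`).
#' @param arm_to_cpg_effect shift of mediator methylation between arms, on the
#'   logit-beta scale.
#' @param cpg_to_outcome_effect outcome effect per unit beta-value per
#'   mediator site, in outcome SD units (before T-score scaling).
#' @param direct_arm_effect residual direct arm effect on the outcomes, in
#'   outcome SD units (0 under full mediation).
#' @param covariate_confounding scale of the baseline-covariate contribution
#'   to the outcomes.
#' @param outcome_noise_sd SD of the independent outcome noise.
#' @param missing_frac fraction of each outcome flagged missing, in
#'   \[0, 0.30\] (the inclusion bound used downstream).
#' @param seed integer seed; generation is a pure function of the config.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_per_arm = c(192L, 211L),
                            n_cpg = 37L,
                            n_mediators = 5L,
                            arm_to_cpg_effect = 0.35,
                            cpg_to_outcome_effect = 1.6,
                            direct_arm_effect = 0,
                            covariate_confounding = 0.6,
                            outcome_noise_sd = 0.5,
                            missing_frac = 0.1,
                            seed = 1L) {
  cfg <- list(n_per_arm = as.integer(n_per_arm), n_cpg = as.integer(n_cpg),
              n_mediators = as.integer(n_mediators),
              arm_to_cpg_effect = arm_to_cpg_effect,
              cpg_to_outcome_effect = cpg_to_outcome_effect,
              direct_arm_effect = direct_arm_effect,
              covariate_confounding = covariate_confounding,
              outcome_noise_sd = outcome_noise_sd,
              missing_frac = missing_frac, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' @noRd
validate_scenario_config <- function(cfg) {
  eff <- c(cfg$arm_to_cpg_effect, cfg$cpg_to_outcome_effect,
           cfg$direct_arm_effect, cfg$covariate_confounding)
  if (any(!is.finite(eff))) stopf("effect sizes must be finite")
  if (length(cfg$n_per_arm) != 2L || any(cfg$n_per_arm < 0L))
    stopf("n_per_arm must be a pair of non-negative integers")
  if (cfg$n_mediators > cfg$n_cpg)
    stopf("n_mediators (%d) exceeds n_cpg (%d)", cfg$n_mediators, cfg$n_cpg)
  if (cfg$missing_frac < 0 || cfg$missing_frac > 0.30)
    stopf(paste("missing_frac must lie in [0, 0.30]: outcomes with more than",
                "30%% missing data are excluded from analysis"))
  if (!is.finite(cfg$outcome_noise_sd) || cfg$outcome_noise_sd <= 0)
    stopf("outcome_noise_sd must be a positive real")
  invisible(cfg)
}

#' Named scenario presets
#'
#' Three presets span the mediation truth table: `"full_mediation"` (the arm
#' affects outcomes only through the mediator CpG-sites),
#' `"partial_mediation"` (mediated plus residual direct arm effect), and
#' `"null"` (the arm affects neither methylation nor outcomes; covariate
#' confounding retained so explanatory-power ratios stay well-defined).
#'
#' @param name one of `"full_mediation"`, `"partial_mediation"`, `"null"`.
#' @param seed integer seed stored in the returned config.
#' @param ... overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name = c("full_mediation", "partial_mediation", "null"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    full_mediation = list(n_mediators = 5L, arm_to_cpg_effect = 0.35,
                          cpg_to_outcome_effect = 1.6, direct_arm_effect = 0,
                          covariate_confounding = 0.6, outcome_noise_sd = 0.5),
    partial_mediation = list(n_mediators = 5L, arm_to_cpg_effect = 0.35,
                             cpg_to_outcome_effect = 1.1, direct_arm_effect = 0.35,
                             covariate_confounding = 0.6, outcome_noise_sd = 0.5),
    null = list(n_mediators = 1L, arm_to_cpg_effect = 0,
                cpg_to_outcome_effect = 0, direct_arm_effect = 0,
                covariate_confounding = 0.8, outcome_noise_sd = 0.5)
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  args$scenario <- NULL
  cfg <- do.call(scenario_config, args)
  attr(cfg, "scenario") <- name
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  nm <- attr(x, "scenario")
  cat("Synthetic cohort scenario", if (!is.null(nm)) sprintf("'%s'", nm), "\n")
  cat(sprintf("  n per arm: %d early-PN / %d late-PN; %d CpG-sites (%d mediators)\n",
              x$n_per_arm[1], x$n_per_arm[2], x$n_cpg, x$n_mediators))
  cat(sprintf("  arm->CpG %.2f (logit), CpG->outcome %.2f, direct %.2f\n",
              x$arm_to_cpg_effect, x$cpg_to_outcome_effect, x$direct_arm_effect))
  cat(sprintf("  confounding %.2f, noise SD %.2f, missing %.0f%%, seed %d\n",
              x$covariate_confounding, x$outcome_noise_sd,
              100 * x$missing_frac, x$seed))
  invisible(x)
}
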