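# Synthetic-cohort generator: treatment -> mediator CpGs -> outcomes, with
# baseline-covariate confounding and MAR outcome missingness.

#' Baseline covariate and outcome column names
#'
#' @export
cohort_covariates <- c("age", "center", "sex", "race", "geographic_origin",
                       "language", "malignancy", "diabetes", "syndrome",
                       "diagnosis", "PIM3", "PeLOD", "STRONGkids")

#' @rdname cohort_covariates
#' @export
cohort_outcomes <- c("internalizing", "externalizing", "total")

#' Generate a synthetic cohort
#'
#' Draws a cohort with the structure the mediation analysis assumes: two
#' randomized arms, thirteen baseline covariates with paediatric-ICU-like
#' distributions, a panel of CpG beta-values generated on the logit scale
#' (site-level means plus patient noise, back-transformed so values stay in
#' (0, 1)), and three correlated continuous behaviour outcomes on a T-score
#' scale (mean 50, SD 10). Mediator sites (the first `n_mediators` panel
#' entries) are shifted between arms by `arm_to_cpg_effect` on the logit
#' scale and drive the outcomes via `cpg_to_outcome_effect`. The total
#' problems score is a weighted sum of the internalizing and externalizing
#' scores plus independent noise. Generation is a pure function of the
#' config (including its seed).
#'
#' @param config a [scenario_config()].
#' @param panel a CpG panel data.frame; defaults to [builtin_cpg_panel()]
#'   (trimmed or extended to `config$n_cpg` sites).
#' @return A data.frame of class `cohort_table`: `patient_id`, `arm`
#'   (factor early-PN / late-PN), the 13 covariates, one beta-value column
#'   per CpG-site, and the three outcome columns. The mediator site ids are
#'   kept in `attr(, "mediators")`.
#' @export
simulate_cohort <- function(config = scenario_config(), panel = builtin_cpg_panel()) {
  validate_scenario_config(config)
  if (nrow(panel) < config$n_cpg)
    stopf("panel has %d sites but n_cpg = %d", nrow(panel), config$n_cpg)
  panel <- panel[seq_len(config$n_cpg), , drop = FALSE]
  n1 <- config$n_per_arm[1]; n2 <- config$n_per_arm[2]; n <- n1 + n2

  cohort <- with_seed(config$seed, {
    arm <- factor(rep(c("early-PN", "late-PN"), c(n1, n2)),
                  levels = c("early-PN", "late-PN"))
    arm01 <- as.numeric(arm == "early-PN")

    # Baseline covariates; proportions and moments follow the cohort the
    # generator emulates (about 40% infants, cardiac-surgery-heavy case mix).
    infant <- rbinom(n, 1, 0.40)
    age <- ifelse(infant == 1, runif(n, 0, 1), runif(n, 1, 17))
    covar <- data.frame(
      age = age,
      center = factor(sample(c("Leuven", "Rotterdam", "Edmonton"), n, TRUE,
                             prob = c(0.6, 0.3, 0.1)),
                      levels = c("Leuven", "Rotterdam", "Edmonton")),
      sex = factor(sample(c("male", "female"), n, TRUE, prob = c(0.585, 0.415)),
                   levels = c("male", "female")),
      race = rbinom(n, 1, 0.05),
      geographic_origin = rbinom(n, 1, 0.17),
      language = rbinom(n, 1, 0.24),
      malignancy = rbinom(n, 1, 0.065),
      diabetes = rbinom(n, 1, 0.01),
      syndrome = rbinom(n, 1, 0.094),
      diagnosis = factor(sample(c("cardiac-surgical", "neurosurgery-trauma",
                                  "thoracic-abdominal", "medical-neurologic",
                                  "medical-respiratory", "other"), n, TRUE,
                                prob = c(0.57, 0.09, 0.09, 0.06, 0.04, 0.15))),
      PIM3 = rnorm(n, -3.6, 1.2),
      PeLOD = rnorm(n, 23.9, 10.3),
      STRONGkids = factor(sample(c("medium", "high"), n, TRUE, prob = c(0.94, 0.06)),
                          levels = c("medium", "high"))
    )

    # Beta-values: logit-normal around site-level means, arm shift additive on
    # the logit scale at mediator sites.
    mu <- rnorm(config$n_cpg, 0, 0.8)
    z <- matrix(rnorm(n * config$n_cpg), n, config$n_cpg)
    z <- sweep(z, 2, mu, "+")
    med_idx <- seq_len(config$n_mediators)
    if (config$arm_to_cpg_effect != 0)
      z[, med_idx] <- z[, med_idx] + config$arm_to_cpg_effect * arm01
    beta <- inv_logit(z)
    colnames(beta) <- panel$cpg_id

    std <- function(v) if (length(v) > 1 && stats::sd(v) > 0)
      (v - mean(v)) / stats::sd(v) else v * 0
    lin <- config$covariate_confounding *
      (0.7 * std(covar$age) + 0.7 * std(covar$PIM3) + 0.3 * covar$syndrome)
    med_mat <- beta[, med_idx, drop = FALSE]
    w_int <- rep(1, config$n_mediators)
    w_ext <- rep_len(c(1.2, 0.8), config$n_mediators)
    med_int <- if (config$cpg_to_outcome_effect != 0)
      config$cpg_to_outcome_effect * as.vector(med_mat %*% w_int) else 0
    med_ext <- if (config$cpg_to_outcome_effect != 0)
      config$cpg_to_outcome_effect * as.vector(med_mat %*% w_ext) else 0

    internal_raw <- lin + med_int + config$direct_arm_effect * arm01 +
      rnorm(n, 0, config$outcome_noise_sd)
    external_raw <- lin + med_ext + config$direct_arm_effect * arm01 +
      rnorm(n, 0, config$outcome_noise_sd)
    total_raw <- 0.5 * (internal_raw + external_raw) +
      rnorm(n, 0, 0.5 * config$outcome_noise_sd)

    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      arm = arm, covar,
      beta,
      internalizing = 50 + 10 * internal_raw,
      externalizing = 50 + 10 * external_raw,
      total = 50 + 10 * total_raw,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    out
  })

  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "cpg_ids") <- panel$cpg_id
  attr(cohort, "mediators") <- panel$cpg_id[seq_len(config$n_mediators)]
  attr(cohort, "config") <- config
  cohort
}

#' Mask outcomes missing-at-random
#'
#' Flags a fixed fraction of each outcome as missing (sets it to `NA`) under
#' a MAR mechanism: the masking probability is logistic in standardized PIM3
#' and age (sicker, younger patients are less likely to complete follow-up
#' testing), and exactly `round(missing_frac * n)` rows are drawn per outcome
#' by weighted sampling without replacement, so the realized fraction matches
#' the target within 1/n. Covariates and CpG values are never masked.
#'
#' @param cohort a `cohort_table`.
#' @param config the [scenario_config()] supplying `missing_frac` and `seed`;
#'   defaults to the config stored in the cohort.
#' @return The cohort with masked outcome cells set to `NA`.
#' @export
inject_missingness <- function(cohort, config = attr(cohort, "config")) {
  validate_scenario_config(config)
  frac <- config$missing_frac
  if (frac == 0) return(cohort)
  n <- nrow(cohort)
  k <- round(frac * n)
  if (k == 0) return(cohort)

  std <- function(v) if (length(v) > 1 && stats::sd(v) > 0)
    (v - mean(v)) / stats::sd(v) else v * 0
  eta <- 0.8 * std(cohort$PIM3) + 0.4 * std(cohort$age)
  # Intercept solved so the mean masking probability hits the target rate.
  a <- stats::uniroot(function(a) mean(inv_logit(a + eta)) - frac,
                      interval = c(-20, 20))$root
  p <- inv_logit(a + eta)

  cohort <- with_seed(derive_seed(config$seed, 7L), {
    for (oc in cohort_outcomes) {
      idx <- sample.int(n, k, prob = p)
      cohort[[oc]][idx] <- NA_real_
    }
    cohort
  })
  cohort
}
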