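# Shared fixtures, built in code at test time.

small_cohort <- function(scenario = "full_mediation", seed = 1,
                         n_per_arm = c(60, 60), missing_frac = 0, ...) {
  cfg <- scenario_preset(scenario, seed = seed, n_per_arm = n_per_arm,
                         missing_frac = missing_frac, ...)
  co <- simulate_cohort(cfg)
  if (missing_frac > 0) co <- inject_missingness(co, cfg)
  co
}

# Independent Wilcoxon oracle: full enumeration of rank assignments.
wilcox_exact_p_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_null <- apply(combos, 2, function(ix) sum(r[ix])) - n * (n + 1) / 2
  mu <- n * m / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu))
}

# One shared cheap mediation fit, built on first use (complete data, m = 1).
fixture_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      co <- small_cohort("full_mediation", seed = 42, n_per_arm = c(100, 100))
      cfg <- mediate_config(n_boot_r2 = 10, n_boot_freq = 15,
                            n_permutations = 19,
                            rf = rf_params(40, min_leaf = 15),
                            rf_importance = rf_params(8, min_leaf = 25),
                            seed = 99)
      fit <<- suppressWarnings(
        mediate_rf(co, outcomes = c("internalizing", "externalizing", "total"),
                   config = cfg))
    }
    fit
  }
})
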