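test_that("generated cohorts have the configured arm sizes, schema and determinism", {
  cfg <- scenario_config(n_per_arm = c(192L, 211L), seed = 7)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$arm == "early-PN"), 192)
  expect_equal(sum(co$arm == "late-PN"), 211)
  expect_true(all(c("patient_id", "arm", cohort_covariates, cohort_outcomes)
                  %in% names(co)))
  betas <- as.matrix(co[, attr(co, "cpg_ids")])
  expect_true(all(betas > 0 & betas < 1))
  expect_false(anyNA(co))

  # empty case keeps the full column schema
  empty <- simulate_cohort(scenario_config(n_per_arm = c(0L, 0L), seed = 1))
  expect_equal(nrow(empty), 0)
  expect_setequal(names(empty), names(co))

  # byte-identical regeneration under the same config
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cfg), f1)
  write_cohort(simulate_cohort(cfg), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("the arm shift at mediator sites is realized on the logit scale", {
  delta <- 0.35
  cfg <- scenario_config(n_per_arm = c(2500L, 2500L), n_mediators = 5L,
                         arm_to_cpg_effect = delta, seed = 11)
  co <- simulate_cohort(cfg)
  e <- co$arm == "early-PN"
  for (site in attr(co, "mediators")) {
    z <- log(co[[site]] / (1 - co[[site]]))
    diff <- mean(z[e]) - mean(z[!e])
    se <- sqrt(var(z[e]) / sum(e) + var(z[!e]) / sum(!e))
    expect_lt(abs(diff - delta), 3 * se)
  }
  # a non-mediator site carries no shift
  other <- setdiff(attr(co, "cpg_ids"), attr(co, "mediators"))[1]
  z <- log(co[[other]] / (1 - co[[other]]))
  se <- sqrt(var(z[e]) / sum(e) + var(z[!e]) / sum(!e))
  expect_lt(abs(mean(z[e]) - mean(z[!e])), 4 * se)
})

test_that("the null scenario carries no arm signal", {
  co <- small_cohort("null", seed = 5, n_per_arm = c(2500, 2500))
  fit <- lm(internalizing ~ arm, data = co)
  expect_lt(summary(fit)$r.squared, 0.01)

  # Monte-Carlo: mean arm/outcome correlation over replicate cohorts ~ 0
  r <- vapply(1:500, function(s) {
    cc <- small_cohort("null", seed = 1000 + s, n_per_arm = c(100, 100))
    cor(as.numeric(cc$arm == "early-PN"), cc$internalizing)
  }, 0)
  expect_lt(abs(mean(r)), 2 / sqrt(200 * 500))
})

test_that("missingness injection is exact-count, conservative and MAR in PIM3", {
  cfg <- scenario_config(n_per_arm = c(200L, 200L), missing_frac = 0.30, seed = 3)
  co <- simulate_cohort(cfg)
  masked <- inject_missingness(co, cfg)
  for (oc in cohort_outcomes)
    expect_lte(abs(sum(is.na(masked[[oc]])) - 120), 1)
  # non-masked cells identical, covariates and CpGs untouched
  keep <- setdiff(names(co), cohort_outcomes)
  expect_identical(masked[, keep], co[, keep])
  for (oc in cohort_outcomes) {
    obs <- !is.na(masked[[oc]])
    expect_identical(masked[[oc]][obs], co[[oc]][obs])
  }
  # zero rate is the identity
  cfg0 <- scenario_config(missing_frac = 0, seed = 3)
  expect_identical(inject_missingness(co, cfg0), co)

  # MAR mechanism: masking is more frequent in the top PIM3 quartile
  big <- scenario_config(n_per_arm = c(1000L, 1000L), missing_frac = 0.25, seed = 9)
  bco <- inject_missingness(simulate_cohort(big), big)
  q <- quantile(bco$PIM3, c(0.25, 0.75))
  top <- mean(is.na(bco$internalizing[bco$PIM3 >= q[2]]))
  bottom <- mean(is.na(bco$internalizing[bco$PIM3 <= q[1]]))
  expect_gt(top, bottom)
})

test_that("the total problems score tracks internalizing plus externalizing", {
  co <- small_cohort("full_mediation", seed = 2, n_per_arm = c(500, 500))
  expect_gt(cor(co$total, co$internalizing + co$externalizing), 0.8)
})

test_that("the builtin panel carries the published sites and valid classes", {
  panel <- builtin_cpg_panel()
  expect_equal(nrow(panel), 37)
  expect_false(anyDuplicated(panel$cpg_id) > 0)
  expect_equal(panel$gene[panel$cpg_id == "cg11047783"], "KAT6B")
  expect_equal(panel$gene[panel$cpg_id == "cg14172797"], "PRKCA")
  expect_true(all(panel$functional_class %in% cpg_functional_classes))
  expect_equal(sum(!panel$placeholder), 13)
  expect_true(all(grepl("^cg[0-9]{8}$", panel$cpg_id)))
})

test_that("invalid scenario configs are rejected", {
  expect_error(scenario_config(n_mediators = 40L), "n_mediators")
  expect_error(scenario_config(missing_frac = 0.4), "30")
  expect_error(scenario_config(arm_to_cpg_effect = Inf), "finite")
  expect_error(scenario_config(outcome_noise_sd = 0), "positive")
})
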