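make_xy <- function(n, p, beta = NULL, noise = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- if (is.null(beta)) rnorm(n, 0, noise)
       else as.vector(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("the forest learns a noiseless signal and is seed-deterministic", {
  d <- make_xy(500, 5, beta = c(2, 0, 0, 0, 0), noise = 0, seed = 2)
  f <- fit_rf(d$X, d$y, rf_params(100, min_leaf = 5), seed = 3)
  expect_gt(f$apparent_r2, 0.9)
  expect_named(f$importance, colnames(d$X))

  f2 <- fit_rf(d$X, d$y, rf_params(100, min_leaf = 5), seed = 3)
  expect_identical(predict(f$fit, data = d$X, num.threads = 1)$predictions,
                   predict(f2$fit, data = d$X, num.threads = 1)$predictions)

  expect_error(fit_rf(d$X, rep(1, 500)), "constant")
  expect_error(fit_rf(d$X[1:10, ], d$y[1:10]), "20 rows")
  dna <- d$X; dna[1, 1] <- NA
  expect_error(fit_rf(dna, d$y), "missing")
})

test_that("out-of-bag R-squared is near zero for pure noise", {
  d <- make_xy(1000, 8, seed = 4)
  f <- fit_rf(d$X, d$y, rf_params(300, min_leaf = 50), seed = 5)
  expect_lt(abs(f$fit$r.squared), 0.05)  # ranger's r.squared is OOB-based
})

test_that("permutation p-values hit the attainable floor for a dominant predictor", {
  d <- make_xy(150, 5, beta = c(3, 0, 0, 0, 0), noise = 0.3, seed = 6)
  p <- permutation_importance_pvalues(d$X, d$y, rf_params(30, min_leaf = 10),
                                      n_permutations = 99, seed = 7)
  expect_equal(unname(p["v1"]), 0.01)  # 1 / (99 + 1)
  expect_true(all(p >= 1 / 100 & p <= 1))

  # pure noise: bounded below by construction, and reproducible
  dn <- make_xy(100, 4, seed = 8)
  p1 <- permutation_importance_pvalues(dn$X, dn$y, rf_params(15, min_leaf = 10),
                                       n_permutations = 19, seed = 9)
  p2 <- permutation_importance_pvalues(dn$X, dn$y, rf_params(15, min_leaf = 10),
                                       n_permutations = 19, seed = 9)
  expect_identical(p1, p2)
  expect_gte(min(p1), 1 / 20)
  expect_error(permutation_importance_pvalues(dn$X, dn$y, n_permutations = 10),
               ">= 19")
})

test_that("the feature-permutation scheme also flags a dominant predictor", {
  d <- make_xy(120, 3, beta = c(3, 0, 0), noise = 0.3, seed = 10)
  p <- permutation_importance_pvalues(d$X, d$y, rf_params(15, min_leaf = 10),
                                      n_permutations = 19, seed = 11,
                                      scheme = "feature")
  expect_equal(unname(p["v1"]), 1 / 20)
  expect_gt(min(p[c("v2", "v3")]), 0.05)
})

test_that("corrected R-squared never exceeds apparent beyond forest noise", {
  for (s in 1:3) {
    d <- make_xy(200, 6, beta = c(1, 1, 0, 0, 0, 0), noise = 1, seed = s)
    r <- suppressWarnings(
      optimism_corrected_r2(d$X, d$y, rf_params(50, min_leaf = 15),
                            n_bootstrap = 20, seed = s))
    expect_lte(r$corrected_r2, r$apparent_r2 + 0.01)
    expect_length(r$optimism, 20)
  }
  # a single replicate is allowed
  d <- make_xy(100, 3, beta = c(1, 0, 0), seed = 9)
  r1 <- optimism_corrected_r2(d$X, d$y, rf_params(25, min_leaf = 10),
                              n_bootstrap = 1, seed = 2)
  expect_true(is.finite(r1$corrected_r2))
})

test_that("fold-increase is plain division with a guarded denominator", {
  expect_equal(fold_increase(0.5, 0.25), 2)
  expect_equal(fold_increase(0.37, 0.37), 1)
  expect_error(fold_increase(0.5, 0), "undefined")
  expect_error(fold_increase(0.5, -0.1), "undefined")
})

test_that("adding the CpG panel does not reduce apparent fit beyond tolerance", {
  co <- small_cohort("full_mediation", seed = 13, n_per_arm = c(100, 100))
  y <- co$internalizing
  Xb <- rfmediate:::encode_covariates(co, include_cpg = FALSE)
  Xc <- rfmediate:::encode_covariates(co, include_cpg = TRUE)
  r_wo <- fit_rf(Xb, y, rf_params(60, min_leaf = 10), seed = 5)$apparent_r2
  r_wi <- fit_rf(Xc, y, rf_params(60, min_leaf = 10), seed = 5)$apparent_r2
  expect_gte(r_wi, r_wo - 0.02)
})

test_that("bootstrap significance counts are bounded, named and reproducible", {
  co <- small_cohort("full_mediation", seed = 15, n_per_arm = c(60, 60))
  X <- rfmediate:::encode_covariates(co)
  y <- co$internalizing
  f1 <- bootstrap_significance_frequencies(X, y, rf_params(8, min_leaf = 25),
                                           n_bootstrap = 5, n_permutations = 19,
                                           seed = 16, strata = co$arm)
  expect_named(f1, colnames(X))
  expect_true(all(f1 >= 0 & f1 <= 5))
  expect_true(all(f1 == round(f1)))
  f2 <- bootstrap_significance_frequencies(X, y, rf_params(8, min_leaf = 25),
                                           n_bootstrap = 5, n_permutations = 19,
                                           seed = 16, strata = co$arm)
  expect_identical(f1, f2)
})
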