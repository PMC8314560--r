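# Random-forest engine: model-matrix encoding, permutation-importance
# p-values, bootstrap optimism-corrected R-squared, significance-frequency
# counting. The forest backend is ranger, always single-threaded and
# explicitly seeded so every result is reproducible.

#' Random-forest hyperparameters
#'
#' Defaults follow the regression conventions for an ensemble of hundreds of
#' trees: 500 trees, `ceiling(p/3)` candidate features per split, minimum
#' leaf size 5. All three are exposed because the analysis they serve states
#' none.
#'
#' @param n_trees number of trees.
#' @param features_per_split candidate features per split (`NULL` =
#'   `ceiling(p/3)` at fit time).
#' @param min_leaf minimum node size.
#' @param splitrule `"variance"` (classic regression forest) or
#'   `"extratrees"` (randomized split points, which damp the
#'   split-selection noise of small samples).
#' @return A list of class `rf_params`.
#' @export
rf_params <- function(n_trees = 500L, features_per_split = NULL, min_leaf = 5L,
                      splitrule = c("variance", "extratrees")) {
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = features_per_split,
                 min_leaf = as.integer(min_leaf),
                 splitrule = match.arg(splitrule)),
            class = "rf_params")
}

# Fixed numeric encoding of the cohort: arm as 0/1 (early-PN = 1), factors
# as integer level codes (trees are order-insensitive in effect, but
# determinism requires a fixed encoding), numerics as-is.
encode_covariates <- function(cohort, include_arm = TRUE, include_cpg = TRUE,
                              covariates = cohort_covariates) {
  cols <- list()
  if (include_arm) cols$arm <- as.numeric(cohort$arm == "early-PN")
  for (v in covariates) {
    val <- cohort[[v]]
    cols[[v]] <- if (is.factor(val)) as.numeric(val)
                 else if (is.character(val)) as.numeric(factor(val))
                 else as.numeric(val)
  }
  X <- do.call(cbind, cols)
  if (include_cpg) {
    cpg <- attr(cohort, "cpg_ids") %||% grep("^cg[0-9]{8}$", names(cohort), value = TRUE)
    X <- cbind(X, as.matrix(cohort[, cpg, drop = FALSE]))
  }
  X
}

#' Fit a random-forest regression
#'
#' Fits a ranger regression forest and reports the apparent R-squared
#' (1 - SSE/SST of the ensemble predictions on the training data) together
#' with impurity-based variable importance. Deterministic under `seed`.
#'
#' @param X numeric covariate matrix (no missing cells, n >= 20).
#' @param y numeric outcome vector.
#' @param params an [rf_params()].
#' @param seed integer seed.
#' @return A list of class `rf_fit`: `fit` (the ranger object),
#'   `apparent_r2`, `importance` (named vector).
#' @export
fit_rf <- function(X, y, params = rf_params(), seed = 1L) {
  if (anyNA(X) || anyNA(y)) stopf("missing cells in model input")
  if (nrow(X) < 20) stopf("need at least 20 rows to fit the forest")
  if (nrow(X) < params$min_leaf) stopf("fewer rows than min_leaf")
  if (stats::var(y) == 0) stopf("outcome is constant (SST = 0)")
  mtry <- min(params$features_per_split %||% ceiling(ncol(X) / 3), ncol(X))
  fit <- ranger::ranger(x = X, y = y, num.trees = params$n_trees, mtry = mtry,
                        min.node.size = params$min_leaf,
                        splitrule = params$splitrule %||% "variance",
                        num.threads = 1, seed = seed, importance = "impurity")
  pred <- stats::predict(fit, data = X, num.threads = 1)$predictions
  structure(list(fit = fit, apparent_r2 = r_squared(y, pred),
                 importance = fit$variable.importance),
            class = "rf_fit")
}

#' Permutation-importance p-values
#'
#' Significance of each covariate's importance against a null distribution
#' of importances obtained by refitting the forest after permuting the
#' outcome vector `n_permutations` times (the default, response-permutation
#' scheme: one permutation refit yields a null importance for every
#' covariate simultaneously). `p = (1 + #\{null >= observed\}) /
#' (1 + n_permutations)`, so p is never 0 and is bounded below by
#' `1/(n_permutations + 1)`. A per-feature permutation scheme (each feature
#' permuted and the forest refitted, `p x n_permutations` refits) is
#' available behind `scheme = "feature"`.
#'
#' @param X,y,params,seed as in [fit_rf()].
#' @param n_permutations number of permutation refits (>= 19).
#' @param scheme `"outcome"` (default) or `"feature"`.
#' @param observed optionally, an existing `rf_fit` on (X, y) whose
#'   importances serve as the observed values (avoids one refit).
#' @return Named vector of p-values in `[1/(n_permutations+1), 1]`.
#' @export
permutation_importance_pvalues <- function(X, y, params = rf_params(),
                                           n_permutations = 200L, seed = 1L,
                                           scheme = c("outcome", "feature"),
                                           observed = NULL) {
  scheme <- match.arg(scheme)
  if (n_permutations < 19) stopf("n_permutations must be >= 19")
  obs_fit <- observed %||% fit_rf(X, y, params, seed)
  obs_imp <- obs_fit$importance
  count_ge <- rep(0, length(obs_imp))
  names(count_ge) <- names(obs_imp)
  if (scheme == "outcome") {
    for (pm in seq_len(n_permutations)) {
      yp <- with_seed(derive_seed(seed, 1000L + pm), sample(y))
      null_fit <- fit_rf(X, yp, params, derive_seed(seed, 2000L + pm))
      count_ge <- count_ge + (null_fit$importance >= obs_imp)
    }
  } else {
    for (j in seq_len(ncol(X))) {
      for (pm in seq_len(n_permutations)) {
        Xp <- X
        Xp[, j] <- with_seed(derive_seed(seed, 10000L + j * 1000L + pm),
                             sample(X[, j]))
        null_fit <- fit_rf(Xp, y, params, derive_seed(seed, 20000L + j * 1000L + pm))
        count_ge[j] <- count_ge[j] + (null_fit$importance[j] >= obs_imp[j])
      }
    }
  }
  (1 + count_ge) / (1 + n_permutations)
}

#' Bootstrap optimism-corrected R-squared
#'
#' Internal validation in the bootstrap-optimism tradition: the apparent
#' R-squared (the ensemble's fit to its own training data) is corrected by
#' subtracting the expected optimism of the modelling procedure. The
#' optimism of replicate `b` is estimated as the apparent R-squared minus
#' the R-squared of a forest refitted on bootstrap resample `b` and
#' evaluated on the original rows not drawn into that resample, so the
#' corrected value equals the mean out-of-resample R-squared. For a
#' flexible learner this out-of-sample contrast is the honest choice: an
#' ensemble partially memorizes rows it has seen, so evaluating replicate
#' models on rows they trained on (in any multiplicity) understates or
#' wildly overstates the optimism depending on leaf size. The corrected
#' value may be negative; it is reported with a warning, never truncated.
#'
#' @param X,y,params,seed as in [fit_rf()].
#' @param n_bootstrap number of bootstrap replicates (>= 1).
#' @param strata optional factor; resampling is stratified within its levels
#'   (e.g. the randomized arm) so both arms survive every replicate.
#' @param apparent_fit optionally, an existing `rf_fit` on (X, y).
#' @return A list: `corrected_r2`, `apparent_r2`, `optimism` (per-replicate
#'   vector).
#' @export
optimism_corrected_r2 <- function(X, y, params = rf_params(),
                                  n_bootstrap = 100L, seed = 1L,
                                  strata = NULL, apparent_fit = NULL) {
  if (n_bootstrap < 1) stopf("n_bootstrap must be >= 1")
  full <- apparent_fit %||% fit_rf(X, y, params, seed)
  n <- length(y)
  optimism <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- bootstrap_indices(n, strata, derive_seed(seed, 300L + b))
    out <- setdiff(seq_len(n), unique(idx))
    if (!length(out)) next  # essentially impossible for n >= 20
    fb <- fit_rf(X[idx, , drop = FALSE], y[idx], params, derive_seed(seed, 400L + b))
    pred_out <- stats::predict(fb$fit, data = X[out, , drop = FALSE],
                               num.threads = 1)$predictions
    optimism[b] <- full$apparent_r2 - r_squared(y[out], pred_out)
  }
  corrected <- full$apparent_r2 - mean(optimism, na.rm = TRUE)
  if (corrected < 0)
    warnf("optimism-corrected R-squared is negative (%.3f); reported unclipped",
          corrected)
  list(corrected_r2 = corrected, apparent_r2 = full$apparent_r2,
       optimism = optimism)
}

bootstrap_indices <- function(n, strata, seed) {
  with_seed(seed, {
    if (is.null(strata)) sample.int(n, n, replace = TRUE)
    else unlist(lapply(split(seq_len(n), strata),
                       function(ix) sample(ix, length(ix), replace = TRUE)),
                use.names = FALSE)
  })
}

#' Fold-increase in explanatory power
#'
#' Ratio of the optimism-corrected R-squared of the model including the
#' CpG panel to that of the model without it.
#'
#' @param r2_with_cpg,r2_without_cpg corrected R-squared values.
#' @return `r2_with_cpg / r2_without_cpg`.
#' @export
fold_increase <- function(r2_with_cpg, r2_without_cpg) {
  if (!is.finite(r2_without_cpg) || r2_without_cpg <= 0)
    stopf("fold-increase undefined: reference R-squared is %s (must be > 0)",
          format(r2_without_cpg))
  r2_with_cpg / r2_without_cpg
}

#' Significance frequencies over bootstrap replicates
#'
#' For each bootstrap resample (with replacement, stratified by `strata`),
#' the forest is refitted and every covariate whose permutation-importance
#' p-value is at or below `alpha` is recorded. Counts are returned per
#' covariate in `[0, n_bootstrap]`. Per-replicate seeds derive from the
#' master seed, so the counts are reproducible.
#'
#' @param X,y,params,seed as in [fit_rf()].
#' @param n_bootstrap number of replicates.
#' @param n_permutations permutation refits per replicate (>= 19).
#' @param alpha significance level (default 0.05).
#' @param strata optional stratification factor for the resampling.
#' @param replicate_data optional function(b) returning `list(X=, y=)` for
#'   replicate `b`, used to rotate replicates across imputed datasets.
#' @return Named integer vector of counts.
#' @export
bootstrap_significance_frequencies <- function(X, y, params = rf_params(),
                                               n_bootstrap = 100L,
                                               n_permutations = 200L,
                                               alpha = 0.05, seed = 1L,
                                               strata = NULL,
                                               replicate_data = NULL) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  counts <- NULL
  for (b in seq_len(n_bootstrap)) {
    dat <- if (is.null(replicate_data)) list(X = X, y = y) else replicate_data(b)
    st <- if (is.null(strata)) NULL else strata
    idx <- bootstrap_indices(length(dat$y), st, derive_seed(seed, 500L + b))
    Xb <- dat$X[idx, , drop = FALSE]; yb <- dat$y[idx]
    p <- permutation_importance_pvalues(Xb, yb, params, n_permutations,
                                        seed = derive_seed(seed, 600L + b))
    sig <- as.integer(p <= alpha)
    counts <- if (is.null(counts)) sig else counts + sig
    names(counts) <- names(p)
  }
  counts
}
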