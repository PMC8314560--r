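# The core analysis: random-forest mediation of a randomized intervention
# through a CpG methylation panel, over a stack of multiply-imputed
# datasets.

#' Configuration for the mediation analysis
#'
#' @param n_boot_r2 bootstrap replicates for the optimism correction.
#' @param n_boot_freq bootstrap replicates for significance-frequency
#'   counting (the two streams are configurable independently).
#' @param n_permutations permutation refits per replicate (>= 19).
#' @param alpha significance level for the frequency counting.
#' @param rf an [rf_params()] for the R-squared/optimism stream.
#' @param rf_importance an [rf_params()] for the permutation-significance
#'   stream; defaults to `rf`. The significance stream is a rank-based
#'   exchangeability test, valid for any forest size, so a smaller forest
#'   may be used there when replication cost matters.
#' @param threshold_frac reporting threshold for calling a covariate
#'   "frequently significant", as a fraction of `n_boot_freq` (default 0.5).
#' @param pool `"paired"` (default; bootstrap replicates rotate round-robin
#'   across the imputed datasets) or `"per_imputation"` (the full bootstrap
#'   is run on every dataset and results are pooled: R-squared via
#'   [rubin_pool_r2()], frequencies averaged and rounded half-to-even).
#' @param stratified stratify the bootstrap resampling by arm (default
#'   `TRUE`) so both arms survive every replicate.
#' @param variants model variants to fit; any of `"base"`, `"base_iv"`,
#'   `"cpg"`, `"cpg_iv"` (baseline risk factors without/with the randomized
#'   intervention, and the same plus the CpG panel).
#' @param freq_variants variants for which significance frequencies are
#'   counted (default the two intervention-containing models).
#' @param seed master seed; all replicate and permutation seeds derive from
#'   it.
#' @return A list of class `mediate_config`.
#' @export
mediate_config <- function(n_boot_r2 = 100L, n_boot_freq = 100L,
                           n_permutations = 200L, alpha = 0.05,
                           rf = rf_params(), rf_importance = NULL,
                           threshold_frac = 0.5,
                           pool = c("paired", "per_imputation"),
                           stratified = TRUE,
                           variants = c("base", "base_iv", "cpg", "cpg_iv"),
                           freq_variants = c("base_iv", "cpg_iv"),
                           seed = 1L) {
  pool <- match.arg(pool)
  variants <- match.arg(variants, several.ok = TRUE)
  if (!all(freq_variants %in% variants))
    stopf("freq_variants must be a subset of variants")
  if (n_permutations < 19) stopf("n_permutations must be >= 19")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (n_boot_r2 < 1 || n_boot_freq < 1) stopf("bootstrap counts must be >= 1")
  structure(list(n_boot_r2 = as.integer(n_boot_r2),
                 n_boot_freq = as.integer(n_boot_freq),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 rf = rf, rf_importance = rf_importance %||% rf,
                 threshold_frac = threshold_frac, pool = pool,
                 stratified = stratified, variants = variants,
                 freq_variants = freq_variants, seed = as.integer(seed)),
            class = "mediate_config")
}

variant_matrix <- function(cohort, variant, cpg_ids) {
  switch(variant,
    base    = encode_covariates(cohort, include_arm = FALSE, include_cpg = FALSE),
    base_iv = encode_covariates(cohort, include_arm = TRUE, include_cpg = FALSE),
    cpg     = encode_covariates(cohort, include_arm = FALSE, include_cpg = TRUE),
    cpg_iv  = encode_covariates(cohort, include_arm = TRUE, include_cpg = TRUE),
    stopf("unknown variant '%s'", variant))
}

#' Random-forest mediation analysis
#'
#' The package's main fitting function. For each outcome and each model
#' variant (baseline risk factors with/without the randomized intervention,
#' each with/without the CpG panel) it computes the bootstrap
#' optimism-corrected R-squared pooled across the imputed datasets, the
#' fold-increase in corrected R-squared attributable to the panel (within
#' each intervention setting), and per-covariate significance frequencies
#' over bootstrap replicates (permutation-importance p <= alpha).
#'
#' Statistical mediation is flagged for an outcome when (i) the intervention
#' is frequently significant in the model without the panel (count at or
#' above `threshold_frac * n_boot_freq`), and (ii) adding the panel lowers
#' the intervention's frequency while at least one CpG-site's frequency
#' reaches the threshold — the panel's methylation status then replaces and
#' outweighs the intervention as a predictor.
#'
#' @param stack an `imputed_stack` from [impute_outcomes()], or a complete
#'   `cohort_table` (treated as a single-dataset stack).
#' @param panel a CpG panel data.frame (see [builtin_cpg_panel()]).
#' @param outcomes outcomes to analyse (default the three behaviour scores).
#'   Outcomes excluded by the 30%-missingness rule are skipped with a
#'   message.
#' @param config a [mediate_config()].
#' @return An object of class `rf_mediation`; see [summary.rf_mediation()].
#'   Key components: `outcomes` (per-outcome results), `frequency_matrix`
#'   (outcomes x covariates significance counts from the with-panel,
#'   with-intervention model), `config`, `panel`.
#' @export
mediate_rf <- function(stack, panel = builtin_cpg_panel(),
                       outcomes = cohort_outcomes,
                       config = mediate_config()) {
  if (inherits(stack, "cohort_table")) {
    if (anyNA(stack[, intersect(outcomes, names(stack))]))
      stopf("cohort has missing outcomes; impute first (impute_outcomes)")
    stack <- structure(list(datasets = list(stack), m = 1L,
                            imputed = character(), excluded = character(),
                            seed = config$seed, iterations = 0L),
                       class = "imputed_stack")
  }
  m <- stack$m
  first <- stack$datasets[[1]]
  cpg_ids <- intersect(panel$cpg_id, names(first))
  if (!length(cpg_ids)) stopf("no panel CpG columns found in the cohort")
  strata <- if (config$stratified) first$arm else NULL

  # covariate matrices are identical across imputations (only outcomes vary)
  Xv <- lapply(stats::setNames(config$variants, config$variants),
               function(v) variant_matrix(first, v, cpg_ids))

  res <- list(); skipped <- character()
  for (oc in outcomes) {
    if (oc %in% stack$excluded || anyNA(first[[oc]])) {
      message(sprintf("outcome '%s' excluded by the 30%% missingness rule; skipped", oc))
      skipped <- c(skipped, oc)
      next
    }
    ys <- lapply(stack$datasets, function(d) d[[oc]])
    oc_seed <- derive_seed(config$seed, match(oc, cohort_outcomes) %||% 1L)
    res[[oc]] <- analyse_outcome(Xv, ys, m, strata, config, oc_seed)
  }
  if (!length(res)) stopf("no analysable outcomes")

  fm <- NULL
  fv <- intersect(c("cpg_iv", "cpg"), config$freq_variants)[1]
  if (!is.na(fv)) {
    fm <- do.call(rbind, lapply(res, function(r) r$frequencies[[fv]]))
    rownames(fm) <- names(res)
  }

  structure(list(outcomes = res, skipped = skipped, frequency_matrix = fm,
                 config = config, panel = panel, m = m),
            class = "rf_mediation")
}

analyse_outcome <- function(Xv, ys, m, strata, config, seed) {
  n <- length(ys[[1]])
  r2 <- list(); freqs <- list()
  neg_warned <- FALSE

  for (v in names(Xv)) {
    X <- Xv[[v]]
    v_seed <- derive_seed(seed, 10L * match(v, c("base", "base_iv", "cpg", "cpg_iv")))
    # one forest seed across imputed datasets: with identical datasets the
    # pooled analysis then reduces exactly to the single-dataset analysis
    apparent <- vapply(seq_len(m), function(d)
      fit_rf(X, ys[[d]], config$rf, derive_seed(v_seed, 5L))$apparent_r2, 0)

    if (config$pool == "paired") {
      # optimism of replicate b measured against the apparent R2 of the
      # dataset it was drawn from; corrected_d = apparent_d - mean optimism
      opt <- rep(NA_real_, config$n_boot_r2)
      for (b in seq_len(config$n_boot_r2)) {
        d <- ((b - 1L) %% m) + 1L
        y <- ys[[d]]
        idx <- bootstrap_indices(n, strata, derive_seed(v_seed, 300L + b))
        out <- setdiff(seq_len(n), unique(idx))
        if (!length(out)) next
        fb <- fit_rf(X[idx, , drop = FALSE], y[idx], config$rf,
                     derive_seed(v_seed, 400L + b))
        pout <- stats::predict(fb$fit, data = X[out, , drop = FALSE],
                               num.threads = 1)$predictions
        opt[b] <- apparent[d] - r_squared(y[out], pout)
      }
      corrected <- apparent - mean(opt, na.rm = TRUE)
    } else {
      per_imp <- lapply(seq_len(m), function(d)
        optimism_corrected_r2(X, ys[[d]], config$rf, config$n_boot_r2,
                              seed = derive_seed(v_seed, 50L + d),
                              strata = strata))
      corrected <- vapply(per_imp, `[[`, 0, "corrected_r2")
    }
    if (any(corrected < 0)) {
      if (!neg_warned) {
        warnf("negative optimism-corrected R-squared clamped to 0 for pooling (variant %s)", v)
        neg_warned <- TRUE
      }
    }
    r2[[v]] <- list(
      corrected = rubin_pool_r2(pmin(pmax(corrected, 0), 1)),
      apparent = rubin_pool_r2(pmin(pmax(apparent, 0), 1)),
      per_imputation = corrected)

    if (v %in% config$freq_variants) {
      f_seed <- derive_seed(v_seed, 7000L)
      if (config$pool == "paired") {
        rep_data <- function(b) list(X = X, y = ys[[((b - 1L) %% m) + 1L]])
        freqs[[v]] <- bootstrap_significance_frequencies(
          X, ys[[1]], config$rf_importance, config$n_boot_freq,
          config$n_permutations, config$alpha, seed = f_seed,
          strata = strata, replicate_data = rep_data)
      } else {
        per_imp <- vapply(seq_len(m), function(d)
          bootstrap_significance_frequencies(
            X, ys[[d]], config$rf_importance, config$n_boot_freq,
            config$n_permutations, config$alpha,
            seed = derive_seed(f_seed, d), strata = strata),
          numeric(ncol(X)))
        freqs[[v]] <- round(rowMeans(per_imp))  # half-to-even
        names(freqs[[v]]) <- colnames(X)
      }
    }
  }

  safe_fold <- function(num, den) tryCatch(fold_increase(num, den),
    error = function(e) { warnf("%s", conditionMessage(e)); NA_real_ })
  folds <- list()
  if (all(c("cpg", "base") %in% names(r2)))
    folds$without_intervention <- safe_fold(r2$cpg$corrected, r2$base$corrected)
  if (all(c("cpg_iv", "base_iv") %in% names(r2)))
    folds$with_intervention <- safe_fold(r2$cpg_iv$corrected, r2$base_iv$corrected)

  thr <- config$threshold_frac * config$n_boot_freq
  iv_base <- if ("base_iv" %in% names(freqs)) unname(freqs$base_iv["arm"]) else NA_real_
  iv_cpg <- if ("cpg_iv" %in% names(freqs)) unname(freqs$cpg_iv["arm"]) else NA_real_
  cpg_max <- if ("cpg_iv" %in% names(freqs))
    max(freqs$cpg_iv[grep("^cg", names(freqs$cpg_iv))]) else NA_real_
  mediation <- !is.na(iv_base) && !is.na(iv_cpg) && !is.na(cpg_max) &&
    iv_base >= thr && iv_cpg < iv_base && cpg_max >= thr

  list(r2 = r2, folds = folds, frequencies = freqs,
       intervention_frequency = c(base = iv_base, with_cpg = iv_cpg),
       max_cpg_frequency = cpg_max, mediation_flag = mediation,
       threshold = thr)
}

#' @export
print.rf_mediation <- function(x, ...) {
  cat(sprintf("Random-forest mediation analysis (m = %d imputation%s, %d/%d bootstrap replicates)\n",
              x$m, if (x$m > 1) "s" else "", x$config$n_boot_r2,
              x$config$n_boot_freq))
  for (oc in names(x$outcomes)) {
    r <- x$outcomes[[oc]]
    fold <- r$folds$with_intervention %||% r$folds$without_intervention
    cat(sprintf("  %-14s corrected R2 (with CpGs%s) = %.3f, fold-increase = %.2f, mediation %s\n",
                oc,
                if (!is.null(r$r2$cpg_iv)) " + intervention" else "",
                (r$r2$cpg_iv %||% r$r2$cpg)$corrected, fold,
                if (r$mediation_flag) "FLAGGED" else "not flagged"))
  }
  if (length(x$skipped))
    cat("  skipped (30% rule):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a mediation analysis
#'
#' @param object an `rf_mediation`.
#' @param ... unused.
#' @return Invisibly, a data.frame with one row per outcome: corrected
#'   R-squared per model variant, fold-increases, intervention significance
#'   frequencies and the mediation flag.
#' @export
summary.rf_mediation <- function(object, ...) {
  tab <- coef(object)
  print(object)
  cat("\nCorrected R-squared by model variant:\n")
  print(round(tab, 3))
  for (oc in names(object$outcomes)) {
    r <- object$outcomes[[oc]]
    cat(sprintf("\n%s: intervention significant in %s/%d replicates without the panel, %s/%d with it (threshold %.0f)\n",
                oc, format(r$intervention_frequency["base"]),
                object$config$n_boot_freq,
                format(r$intervention_frequency["with_cpg"]),
                object$config$n_boot_freq, r$threshold))
  }
  invisible(tab)
}

#' Corrected R-squared table of a mediation analysis
#'
#' @param object an `rf_mediation`.
#' @param ... unused.
#' @return Matrix: outcomes x model variants, pooled optimism-corrected
#'   R-squared.
#' @export
coef.rf_mediation <- function(object, ...) {
  variants <- object$config$variants
  t(vapply(object$outcomes, function(r)
    vapply(variants, function(v) r$r2[[v]]$corrected, 0), numeric(length(variants))))
}

#' Heatmap of the significance-frequency matrix
#'
#' Clusters the outcome-by-covariate frequency matrix and draws the
#' annotated heatmap (see [cluster_frequency_matrix()] and
#' [render_heatmap()]).
#'
#' @param x an `rf_mediation`.
#' @param path optional file path; if `NULL`, plots to the active device.
#' @param cpg_only restrict columns to the CpG panel (default `TRUE`).
#' @param ... passed to [render_heatmap()].
#' @export
plot.rf_mediation <- function(x, path = NULL, cpg_only = TRUE, ...) {
  fm <- frequency_matrix(x, cpg_only = cpg_only)
  cr <- cluster_frequency_matrix(fm)
  render_heatmap(fm, cr, panel = x$panel, path = path,
                 n_bootstrap = x$config$n_boot_freq, ...)
}

#' Extract the significance-frequency matrix
#'
#' @param x an `rf_mediation`.
#' @param cpg_only keep only CpG columns (default `TRUE`).
#' @return Integer matrix, outcomes x covariates.
#' @export
frequency_matrix <- function(x, cpg_only = TRUE) {
  fm <- x$frequency_matrix
  if (is.null(fm)) stopf("no frequency matrix: no freq_variants were computed")
  if (cpg_only) fm <- fm[, grep("^cg", colnames(fm)), drop = FALSE]
  fm
}
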