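# Multiple imputation of outcome missingness by chained equations with
# predictive mean matching, and Rubin-style pooling of R-squared.

#' Chained-equations multiple imputation of outcomes
#'
#' Produces `m` completed copies of a cohort. Each incomplete outcome is
#' regressed on all available data per patient — arm, the baseline
#' covariates, the CpG beta-values and the other outcomes at their current
#' working values — and imputed by predictive mean matching: regression
#' coefficients are drawn from their approximate posterior (proper
#' imputation, so between-imputation variance is positive), predicted means
#' are computed for incomplete and observed rows, and each missing cell
#' receives the observed value of one of the `k` nearest donors. The
#' chained cycle is iterated `iterations` times before the dataset is kept.
#'
#' Outcomes with more than 30% missing data are excluded from imputation
#' (and should be excluded from downstream modelling); they are reported
#' with a warning, not an error. An all-missing outcome is an error.
#' Observed cells are never altered. Per-imputation seeds are derived from
#' the master seed by a fixed offset, so increasing `m` extends the stack
#' without reshuffling earlier datasets.
#'
#' @param cohort a `cohort_table` (covariates and beta-values complete).
#' @param m number of imputed datasets (default 31).
#' @param iterations chained-equation cycles per dataset (default 10).
#' @param seed master seed.
#' @param k number of predictive-mean-matching donors (default 5).
#' @return An object of class `imputed_stack`: `datasets` (list of `m`
#'   completed cohorts), `m`, `imputed` (outcomes imputed), `excluded`
#'   (outcomes over the 30% bound), `trace` (per-dataset, per-iteration,
#'   per-outcome mean of the imputed values), `seed`, `iterations`.
#' @export
impute_outcomes <- function(cohort, m = 31L, iterations = 10L, seed = 1L, k = 5L) {
  if (m < 1) stopf("m must be >= 1")
  n <- nrow(cohort)
  miss_frac <- vapply(cohort_outcomes, function(oc) mean(is.na(cohort[[oc]])), 0)
  if (any(miss_frac == 1)) stopf("outcome %s is entirely missing",
                                 names(miss_frac)[miss_frac == 1][1])
  excluded <- names(miss_frac)[miss_frac > 0.30]
  if (length(excluded))
    warnf("outcome(s) %s exceed 30%% missing data and are excluded from imputation (inclusion bound: only outcomes with <= 30%% missing data)",
          paste(sprintf("%s (%.0f%%)", excluded, 100 * miss_frac[excluded]),
                collapse = ", "))
  targets <- setdiff(names(miss_frac)[miss_frac > 0], excluded)

  X_base <- encode_covariates(cohort)  # arm + covariates + CpGs, numeric
  trace <- array(NA_real_, dim = c(m, iterations, length(targets)),
                 dimnames = list(NULL, NULL, targets))

  datasets <- vector("list", m)
  for (d in seq_len(m)) {
    if (!length(targets)) { datasets[[d]] <- cohort; next }
    datasets[[d]] <- with_seed(derive_seed(seed, 100L + d), {
      work <- cohort
      # initialize missing cells with random observed values
      for (oc in targets) {
        idx <- which(is.na(work[[oc]]))
        obs <- work[[oc]][!is.na(work[[oc]])]
        work[[oc]][idx] <- sample(obs, length(idx), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (oc in targets) {
          mis <- which(is.na(cohort[[oc]]))
          obs <- which(!is.na(cohort[[oc]]))
          others <- setdiff(intersect(cohort_outcomes, names(work)), c(oc, excluded))
          X <- cbind(X_base, as.matrix(work[, others, drop = FALSE]))
          work[[oc]][mis] <- pmm_draw(X, cohort[[oc]], obs, mis, k)
          trace[d, it, oc] <- mean(work[[oc]][mis])
        }
      }
      work
    })
  }

  structure(list(datasets = datasets, m = as.integer(m), imputed = targets,
                 excluded = excluded, trace = trace,
                 seed = as.integer(seed), iterations = as.integer(iterations)),
            class = "imputed_stack")
}

# One predictive-mean-matching draw for the missing cells of one variable.
# Coefficients are drawn from the approximate Bayesian posterior of the
# least-squares fit (scaled inverse-chi-square sigma^2, Gaussian beta), the
# predicted means of the missing rows under the drawn coefficients are
# matched against the observed rows' fitted means, and one of the k nearest
# donors is sampled per missing row.
pmm_draw <- function(X, y, obs, mis, k) {
  Xo <- cbind(1, X[obs, , drop = FALSE])
  qr_o <- qr(Xo)
  keep <- qr_o$pivot[seq_len(qr_o$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, y[obs])
  beta_hat <- fit$coefficients
  df <- length(obs) - length(beta_hat)
  sigma2 <- sum(fit$residuals^2) / max(df, 1)
  sigma2_star <- sum(fit$residuals^2) / stats::rchisq(1, max(df, 1))
  R <- qr.R(qr(Xo))
  # beta* ~ N(beta_hat, sigma2* (X'X)^-1); solve against the Cholesky factor
  beta_star <- beta_hat + sqrt(sigma2_star) *
    backsolve(R, stats::rnorm(length(beta_hat)))
  Xm <- cbind(1, X[mis, , drop = FALSE])[, keep, drop = FALSE]
  yhat_obs <- as.vector(Xo %*% beta_hat)
  yhat_mis <- as.vector(Xm %*% beta_star)
  vapply(yhat_mis, function(mu) {
    donors <- order(abs(yhat_obs - mu))[seq_len(min(k, length(obs)))]
    y[obs][sample(donors, 1)]
  }, 0)
}

#' Rubin-style pooling of R-squared across imputations
#'
#' Each R-squared is mapped to a multiple correlation `r = sqrt(R2)`,
#' Fisher-z transformed, the z-values averaged (Rubin's point-estimate
#' rule), back-transformed and squared. The pooled value always lies within
#' the range of the inputs and is invariant to their order. The transform is
#' the Harel approach for pooling R-squared; it is the package's documented
#' choice of scale for the averaging.
#'
#' @param r2_values numeric vector of R-squared values in \[0, 1\].
#' @return The pooled R-squared.
#' @export
rubin_pool_r2 <- function(r2_values) {
  if (!length(r2_values)) stopf("empty input")
  if (any(!is.finite(r2_values)) || any(r2_values < 0) || any(r2_values > 1))
    stopf("all R-squared values must lie in [0, 1]")
  # atanh(1) is infinite; an input of exactly 1 can only pool with other 1s
  if (any(r2_values == 1)) {
    if (all(r2_values == 1)) return(1)
    r2_values <- pmin(r2_values, 1 - 1e-12)
  }
  tanh(mean(atanh(sqrt(r2_values))))^2
}

#' Serialize / load an imputed stack
#'
#' Writes one CSV per completed dataset plus a `manifest.json` recording
#' `m`, the master seed, iteration count and excluded outcomes.
#'
#' @param stack an `imputed_stack`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in seq_len(stack$m))
    utils::write.csv(as.data.frame(stack$datasets[[d]]),
                     file.path(dir, sprintf("imputed_%03d.csv", d)),
                     row.names = FALSE)
  jsonlite::write_json(
    list(m = stack$m, seed = stack$seed, iterations = stack$iterations,
         imputed = stack$imputed, excluded = stack$excluded),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("Imputed stack: m = %d datasets, %d chained iterations, seed %d\n",
              x$m, x$iterations, x$seed))
  cat("Imputed outcomes:", if (length(x$imputed)) paste(x$imputed, collapse = ", ")
      else "(none)", "\n")
  if (length(x$excluded))
    cat("Excluded (> 30% missing):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
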