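# Cohort table I/O: tidy CSV with a fixed, documented schema.

#' Write / read a cohort table
#'
#' The on-disk format is a tidy CSV: one row per patient, one column per
#' field (`patient_id`, `arm`, the thirteen baseline covariates, one
#' beta-value column per CpG-site named by its probe id, and the three
#' outcome columns). A JSON sidecar (`<path>.json`) echoes the generating
#' scenario config when one is attached, so simulated files are
#' self-describing.
#'
#' @param cohort a `cohort_table`.
#' @param path file path for the CSV.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   validated `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    side <- unclass(cfg)
    side$scenario <- attr(cfg, "scenario")
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "arm", cohort_covariates, cohort_outcomes)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("cohort file lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stopf("duplicate patient_id: %s",
          paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  if (any(is.na(df$arm)))
    stopf("row(s) with missing arm: %s",
          paste(which(is.na(df$arm)), collapse = ", "))
  bad_arm <- setdiff(unique(df$arm), c("early-PN", "late-PN"))
  if (length(bad_arm)) stopf("unknown arm label: %s", paste(bad_arm, collapse = ", "))
  df$arm <- factor(df$arm, levels = c("early-PN", "late-PN"))
  for (v in c("center", "sex", "diagnosis", "STRONGkids"))
    df[[v]] <- factor(df[[v]])

  cpg_cols <- grep("^cg[0-9]{8}$", names(df), value = TRUE)
  for (cc in cpg_cols) {
    bad <- which(!is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] > 1))
    if (length(bad))
      stopf("beta-value outside [0, 1] in column %s, row %s", cc,
            paste(bad, collapse = ", "))
    if (anyNA(df[[cc]]))
      stopf("missing beta-value in column %s (only outcomes may be missing)", cc)
  }
  for (v in cohort_covariates) if (anyNA(df[[v]]))
    stopf("missing covariate %s (only outcomes may be missing)", v)

  class(df) <- c("cohort_table", "data.frame")
  attr(df, "cpg_ids") <- cpg_cols
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cpg <- attr(x, "cpg_ids") %||% grep("^cg[0-9]{8}$", names(x), value = TRUE)
  cat(sprintf("Cohort: %d patients (%d early-PN / %d late-PN), %d CpG-sites\n",
              nrow(x), sum(x$arm == "early-PN"), sum(x$arm == "late-PN"),
              length(cpg)))
  nmiss <- vapply(cohort_outcomes, function(oc) sum(is.na(x[[oc]])), 0L)
  cat("Outcome missingness:",
      paste(sprintf("%s %d", cohort_outcomes, nmiss), collapse = ", "), "\n")
  invisible(x)
}
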