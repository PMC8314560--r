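# Baseline-comparison statistics: Wilcoxon rank-sum for continuous
# variables, Pearson chi-square for proportions.

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction (the convention used for
#' the baseline-comparison tables), df = (rows - 1)(cols - 1), p-value from
#' the upper tail of the chi-square distribution. A flag enables the Yates
#' correction for 2x2 tables.
#'
#' @param tab a matrix of non-negative counts with all row and column
#'   margins positive.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("degenerate table: a row or column margin is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks are used for ties. The p-value is exact (by enumeration over
#' rank assignments) when the pooled sample size is at most 12 and there are
#' no ties, and otherwise uses the continuity-corrected normal approximation
#' with tie correction.
#'
#' @param x,y non-empty numeric vectors.
#' @return A list with `statistic` (the Mann-Whitney U of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = unname(wt$p.value))
}

#' Baseline-comparison table
#'
#' Summarizes each requested variable per arm — mean (SD) for continuous
#' variables, n (%) per level for categorical ones — with a two-sided
#' p-value from the Wilcoxon rank-sum test (continuous) or the Pearson
#' chi-square test (categorical). Missing categorical values are reported
#' and tested as an explicit `"unknown"` level.
#'
#' @param cohort a `cohort_table`.
#' @param variables character vector of column names to summarize; defaults
#'   to the thirteen baseline covariates.
#' @return A data.frame of class `baseline_table` with one row per variable
#'   (continuous) or per variable level (categorical): `variable`, `level`,
#'   `early_PN`, `late_PN`, `test`, `statistic`, `p_value` (p repeated
#'   across the levels of one variable).
#' @export
baseline_table <- function(cohort, variables = cohort_covariates) {
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown))
    stopf("unknown variable(s): %s", paste(unknown, collapse = ", "))
  e <- cohort$arm == "early-PN"
  rows <- list()
  for (v in variables) {
    val <- cohort[[v]]
    if (is.numeric(val) && length(unique(val[!is.na(val)])) > 6) {
      ts <- wilcoxon_rank_sum(val[e], val[!e])
      rows[[v]] <- data.frame(
        variable = v, level = "",
        early_PN = sprintf("%.1f (%.1f)", mean(val[e], na.rm = TRUE),
                           stats::sd(val[e], na.rm = TRUE)),
        late_PN = sprintf("%.1f (%.1f)", mean(val[!e], na.rm = TRUE),
                          stats::sd(val[!e], na.rm = TRUE)),
        test = "wilcoxon", statistic = ts$statistic, p_value = ts$p_value,
        stringsAsFactors = FALSE)
    } else {
      f <- factor(val)
      if (anyNA(f)) {
        f <- factor(f, levels = c(levels(f), "unknown"))
        f[is.na(f)] <- "unknown"
      }
      tab <- table(cohort$arm, f)
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2) {  # no variation: homogeneous by construction
        ts <- list(statistic = 0, p_value = 1)
      } else {
        ts <- chi_square_test(tab)
      }
      lev <- colnames(tab)
      rows[[v]] <- data.frame(
        variable = v, level = lev,
        early_PN = sprintf("%d (%.1f%%)", tab["early-PN", ],
                           100 * tab["early-PN", ] / sum(e)),
        late_PN = sprintf("%d (%.1f%%)", tab["late-PN", ],
                          100 * tab["late-PN", ] / sum(!e)),
        test = "chi_square", statistic = ts$statistic, p_value = ts$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Write a baseline table as CSV and Markdown
#'
#' @param tab a `baseline_table`.
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.md`.
#' @return `path`, invisibly.
#' @export
write_baseline_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), paste0(path, ".csv"), row.names = FALSE)
  md <- c("| Variable | Level | Early-PN | Late-PN | P value |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s | %s | %s | %s |", tab$variable, tab$level,
                  tab$early_PN, tab$late_PN,
                  ifelse(duplicated(tab$variable), "",
                         formatC(tab$p_value, digits = 3, format = "fg"))))
  writeLines(md, paste0(path, ".md"))
  invisible(path)
}
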