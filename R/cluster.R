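# Hierarchical clustering of the significance-frequency matrix and the
# annotated heatmap / report that summarize a mediation analysis.

#' Cluster a significance-frequency matrix
#'
#' Agglomerative clustering of rows (outcomes) and columns (covariates or
#' CpG-sites) independently, on the raw frequency values. Rows and columns
#' are sorted by label before distances are computed, so the result is
#' invariant to the input ordering and ties are broken deterministically by
#' label order.
#'
#' @param fm numeric matrix with unique row and column names; values are
#'   significance counts in `[0, n_bootstrap]`.
#' @param metric distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return A list of class `freq_clustering`: `row_order` and `col_order`
#'   (label permutations), `row_tree` and `col_tree` (hclust objects with
#'   non-decreasing merge heights).
#' @export
cluster_frequency_matrix <- function(fm, metric = "euclidean",
                                     linkage = "average") {
  fm <- as.matrix(fm)
  if (nrow(fm) < 2 || ncol(fm) < 2)
    stopf("degenerate matrix: need at least 2 rows and 2 columns to cluster")
  if (is.null(rownames(fm)) || is.null(colnames(fm)) ||
      anyDuplicated(rownames(fm)) || anyDuplicated(colnames(fm)))
    stopf("row and column names must be present and unique")
  fm <- fm[order(rownames(fm)), order(colnames(fm)), drop = FALSE]
  row_tree <- stats::hclust(stats::dist(fm, method = metric), method = linkage)
  col_tree <- stats::hclust(stats::dist(t(fm), method = metric), method = linkage)
  structure(list(row_order = rownames(fm)[row_tree$order],
                 col_order = colnames(fm)[col_tree$order],
                 row_tree = row_tree, col_tree = col_tree,
                 metric = metric, linkage = linkage),
            class = "freq_clustering")
}

#' @export
print.freq_clustering <- function(x, ...) {
  cat(sprintf("Frequency-matrix clustering (%s distance, %s linkage)\n",
              x$metric, x$linkage))
  cat("Row order:", paste(x$row_order, collapse = ", "), "\n")
  cat("Column order:", paste(utils::head(x$col_order, 8), collapse = ", "),
      if (length(x$col_order) > 8) "...", "\n")
  invisible(x)
}

#' Render the clustered frequency heatmap
#'
#' Draws the outcome-by-CpG significance-frequency matrix as a heatmap with
#' row and column dendrograms, a sequential white-to-orange colour ramp
#' scaled from 0 to `n_bootstrap` (darker orange = higher frequency), and a
#' functional-class colour strip under the column dendrogram. When `path`
#' is given, the figure is written there (format by extension: .png, .pdf,
#' or .tiff) together with a machine-readable JSON sidecar
#' (`<path>.json`) recording the row/column orders and the matrix, so the
#' figure's structure can be checked and reproduced without parsing the
#' image.
#'
#' @param fm frequency matrix (outcomes x CpG-sites).
#' @param cr a `freq_clustering` for `fm`; computed if `NULL`.
#' @param panel CpG panel supplying `functional_class` per column.
#' @param path output file, or `NULL` to plot to the active device.
#' @param n_bootstrap colour-scale maximum (defaults to `max(fm)`).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The path (or the pheatmap object when `path` is `NULL`),
#'   invisibly.
#' @export
render_heatmap <- function(fm, cr = NULL, panel = builtin_cpg_panel(),
                           path = NULL, n_bootstrap = NULL, ...) {
  fm <- as.matrix(fm)
  if (is.null(cr)) cr <- cluster_frequency_matrix(fm)
  missing_ann <- setdiff(colnames(fm), panel$cpg_id)
  if (length(missing_ann))
    stopf("no panel annotation for column(s): %s",
          paste(utils::head(missing_ann, 5), collapse = ", "))
  top <- n_bootstrap %||% max(fm, 1)
  oranges <- grDevices::colorRampPalette(
    c("#FFF5EB", "#FDD0A2", "#FD8D3C", "#D94801", "#7F2704"))(64)
  ann <- data.frame(class = panel$functional_class[match(colnames(fm), panel$cpg_id)],
                    row.names = colnames(fm))
  class_cols <- stats::setNames(
    grDevices::hcl.colors(length(cpg_functional_classes), "Dark 3"),
    cpg_functional_classes)
  # pheatmap wants the data in the pre-sorted order its trees were built on
  fm_sorted <- fm[order(rownames(fm)), order(colnames(fm)), drop = FALSE]
  args <- list(mat = fm_sorted, cluster_rows = cr$row_tree,
               cluster_cols = cr$col_tree, color = oranges,
               breaks = seq(0, top, length.out = 65),
               annotation_col = ann,
               annotation_colors = list(class = class_cols[unique(ann$class)]),
               silent = !is.null(path), ...)
  if (!is.null(path)) args$filename <- path
  ph <- do.call(pheatmap::pheatmap, args)
  if (!is.null(path)) {
    jsonlite::write_json(
      list(row_order = cr$row_order, col_order = cr$col_order,
           n_bootstrap = top,
           matrix = stats::setNames(as.data.frame(fm), colnames(fm)),
           rows = rownames(fm)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  invisible(ph)
}

#' Read back a heatmap sidecar
#'
#' @param path the heatmap file path (sidecar at `<path>.json`).
#' @return A list with `row_order`, `col_order`, and the frequency `matrix`.
#' @export
read_heatmap_sidecar <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fm <- as.matrix(side$matrix)
  rownames(fm) <- side$rows
  list(row_order = side$row_order, col_order = side$col_order,
       matrix = fm, n_bootstrap = side$n_bootstrap)
}

#' Write a Markdown report of a mediation analysis
#'
#' Assembles the corrected-R-squared / fold-increase table per outcome, the
#' intervention significance frequencies, the mediation flags (with the
#' flagging rule stated), the top-ranked CpG-sites per outcome, and a link
#' to the clustered heatmap. Regeneration from the same fitted object is
#' byte-identical.
#'
#' @param fit an `rf_mediation`.
#' @param path output file (Markdown).
#' @param heatmap optional path of a rendered heatmap to reference.
#' @param top_n CpG-sites listed per outcome (default 5).
#' @return `path`, invisibly.
#' @export
report_mediation <- function(fit, path, heatmap = NULL, top_n = 5) {
  if (!length(fit$outcomes)) stopf("empty results: nothing to report")
  cfg <- fit$config
  lines <- c("# Methylation mediation report", "",
             sprintf("Imputed datasets: %d; bootstrap replicates: %d (R2) / %d (frequencies); permutations: %d; alpha = %.2f.",
                     fit$m, cfg$n_boot_r2, cfg$n_boot_freq, cfg$n_permutations,
                     cfg$alpha), "",
             "## Explanatory power (optimism-corrected R2)", "",
             "| Outcome | R2 without intervention | Fold-increase | R2 with intervention | Fold-increase |",
             "|---|---|---|---|---|")
  for (oc in names(fit$outcomes)) {
    r <- fit$outcomes[[oc]]
    fmtn <- function(z) if (is.null(z)) "-" else sprintf("%.3f", z)
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |", oc,
                              fmtn(r$r2$cpg$corrected),
                              fmtn(r$folds$without_intervention),
                              fmtn(r$r2$cpg_iv$corrected),
                              fmtn(r$folds$with_intervention)))
  }
  lines <- c(lines, "",
             "R2 of the models including the CpG panel; fold-increase relative to the model with baseline risk factors only (same intervention setting).",
             "", "## Mediation assessment", "",
             sprintf("Rule: mediation is flagged when the intervention is significant in at least %.0f of %d replicates without the panel, its frequency drops when the panel is added, and at least one CpG-site reaches the threshold.",
                     fit$outcomes[[1]]$threshold, cfg$n_boot_freq), "")
  for (oc in names(fit$outcomes)) {
    r <- fit$outcomes[[oc]]
    lines <- c(lines, sprintf("- **%s**: intervention %s/%d -> %s/%d with panel; max CpG frequency %s; mediation %s.",
                              oc, format(r$intervention_frequency["base"]),
                              cfg$n_boot_freq,
                              format(r$intervention_frequency["with_cpg"]),
                              cfg$n_boot_freq, format(r$max_cpg_frequency),
                              if (r$mediation_flag) "**flagged**" else "not flagged"))
  }
  lines <- c(lines, "", "## Top CpG-sites per outcome", "")
  fm <- frequency_matrix(fit)
  for (oc in rownames(fm)) {
    top <- sort(fm[oc, ], decreasing = TRUE)[seq_len(min(top_n, ncol(fm)))]
    gene <- fit$panel$gene[match(names(top), fit$panel$cpg_id)]
    lines <- c(lines, sprintf("- %s: %s", oc,
                              paste(sprintf("%s (%s, %d)", names(top), gene, top),
                                    collapse = ", ")))
  }
  if (length(fit$skipped))
    lines <- c(lines, "", sprintf("Outcomes excluded by the 30%% missingness rule: %s.",
                                  paste(fit$skipped, collapse = ", ")))
  if (!is.null(heatmap))
    lines <- c(lines, "", sprintf("![Clustered significance-frequency heatmap](%s)",
                                  basename(heatmap)))
  writeLines(lines, path)
  invisible(path)
}
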