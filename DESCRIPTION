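Package: rfmediate
Title: Random-Forest Mediation Analysis of DNA Methylation Panels in
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much of a randomized intervention's effect on
    continuous outcomes is statistically explained by a panel of candidate
    mediator CpG-sites. Random-forest regression models are fitted with and
    without the methylation panel and with and without the randomized arm;
    covariate significance is assessed by permutation-importance p-values,
    explanatory power by bootstrap optimism-corrected R-squared with
    fold-increase, robustness by significance-frequency counting over
    bootstrap replicates, and outcome missingness is handled by chained-
    equations multiple imputation with Rubin-style pooling of R-squared.
    Includes a synthetic-cohort generator with named scenarios (full,
    partial and null mediation), baseline-comparison statistics, and
    hierarchical clustering of the significance-frequency matrix with an
    annotated heatmap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    pheatmap,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
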