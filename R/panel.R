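#' Functional classes used to annotate CpG panels
#'
#' The eight classes used for the column annotation of the significance-
#' frequency heatmap.
#'
#' @export
cpg_functional_classes <- c(
  "Cerebral/neuronal",
  "Growth/Development/Locomotion",
  "Metabolism",
  "Gene expression/DNA regulation/Epigenetic regulation",
  "Intra/intercellular Signaling/Transport",
  "Non-coding RNA/pseudogene",
  "Oncogenic/Apoptosis",
  "Intergenic"
)

#' Built-in 37-site CpG panel
#'
#' Returns the panel of 37 differentially methylated CpG-sites used throughout
#' the package. Thirteen sites carry their published probe id and gene symbol
#' (PRKCA, KAT6B, CEP85L, PLD3, srGAP1, FNBP1, TCF7L2, NLRC5, THADA, RNF217,
#' PLA2G15, ZSCAN25, SLC35E1); the remaining 24 sites of the panel are not
#' individually published and are shipped as synthetic placeholder probes
#' (`placeholder = TRUE`) with functional classes spread over the eight
#' annotation classes, including intergenic and non-coding sites.
#'
#' @return A data.frame with columns `cpg_id`, `gene`, `functional_class`,
#'   `placeholder`; 37 rows, unique `cpg_id`.
#' @export
builtin_cpg_panel <- function() {
  named <- data.frame(
    cpg_id = c("cg14172797", "cg11047783", "cg14109551", "cg14450616",
               "cg26308668", "cg14364797", "cg22645359", "cg12928479",
               "cg22076676", "cg01842756", "cg16301196", "cg07375256",
               "cg26683792"),
    gene = c("PRKCA", "KAT6B", "CEP85L", "PLD3", "srGAP1", "FNBP1", "TCF7L2",
             "NLRC5", "THADA", "RNF217", "PLA2G15", "ZSCAN25", "SLC35E1"),
    functional_class = c(
      "Cerebral/neuronal",            # PRKCA: memory, mood regulation
      "Cerebral/neuronal",            # KAT6B: cortex development
      "Cerebral/neuronal",            # CEP85L
      "Cerebral/neuronal",            # PLD3: neuronal development
      "Cerebral/neuronal",            # srGAP1: neuronal migration
      "Cerebral/neuronal",            # FNBP1: neuronal networks
      "Growth/Development/Locomotion",# TCF7L2: Wnt signalling
      "Intra/intercellular Signaling/Transport", # NLRC5: neuroimmune
      "Oncogenic/Apoptosis",          # THADA
      "Oncogenic/Apoptosis",          # RNF217
      "Metabolism",                   # PLA2G15: lipid metabolism
      "Gene expression/DNA regulation/Epigenetic regulation", # ZSCAN25
      "Intra/intercellular Signaling/Transport"  # SLC35E1: transporter
    ),
    placeholder = FALSE,
    stringsAsFactors = FALSE
  )
  # 24 placeholder sites: deterministic synthetic ids, classes cycled over the
  # full class set with extra weight on intergenic / non-coding sites.
  n_extra <- 24L
  extra_class <- rep(cpg_functional_classes, length.out = 16L)
  extra_class <- c(extra_class, rep(c("Intergenic", "Non-coding RNA/pseudogene"), each = 4L))
  extra <- data.frame(
    cpg_id = sprintf("cg9%07d", seq_len(n_extra)),
    gene = ifelse(extra_class == "Intergenic", "intergenic",
                  sprintf("SYNTH%02d", seq_len(n_extra))),
    functional_class = extra_class,
    placeholder = TRUE,
    stringsAsFactors = FALSE
  )
  panel <- rbind(named, extra)
  rownames(panel) <- NULL
  validate_cpg_panel(panel)
  panel
}

#' @noRd
validate_cpg_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("cpg_id", "gene", "functional_class") %in% names(panel)))
  if (anyDuplicated(panel$cpg_id)) stopf("duplicate cpg_id in panel")
  bad <- setdiff(unique(panel$functional_class), cpg_functional_classes)
  if (length(bad)) stopf("unknown functional class: %s", paste(bad, collapse = ", "))
  invisible(panel)
}
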