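Package: striacell
Title: Striatal Interneuron Single-Cell Taxonomy and PatchSeq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying striatal interneurons from single-cell
    UMI count matrices and for linking transcriptomes to intrinsic
    electrophysiology measured by PatchSeq. Implements dataset-specific
    quality-control cascades, total-count normalization, variable-gene
    selection, a pluggable clustering stage with classifier-based
    robustness assessment, marker-gene enrichment scoring and gene-by-type
    specificity, a rank-1 negative-binomial latent-factor model for
    within-cluster expression gradients with batch covariates, Spearman
    correlation and Wilcoxon rank-sum differential-expression screens with
    Benjamini-Hochberg control, specificity-weighted bootstrap assignment
    of PatchSeq transcriptomes to reference cell types, and extraction of
    intrinsic electrophysiological parameters from current-clamp sweeps.
    Synthetic-data generators with known ground truth accompany every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    randomForest,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
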