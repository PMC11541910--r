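Package: adipotraj
Title: Subpopulation Structure and Differentiation Trajectories of
    Adipocyte Progenitors from Droplet scRNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for droplet single-cell RNA-seq analysis
    of PDGFRA+ adipocyte-progenitor heterogeneity: barcode-rank knee-point
    filtering of empty droplets, cell-level quality control, pooled
    (deconvolution) size-factor normalization, mean-variance decomposition
    for highly variable gene selection with batch design matrices, immune
    pre-filtering, shared-nearest-neighbor graph clustering and merging of
    clusters into groups, two-stage marker identification combining Wilcoxon
    screening with a PLS-DA variable-importance-in-projection (VIP)
    permutation test against a Gaussian kernel density null, principal-tree
    pseudotime with early/middle/late gene-program classification along
    linear and bifurcating trajectories, and local EASE-score gene-set
    enrichment. Includes a synthetic droplet-data generator that plants
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    scran,
    igraph,
    jsonlite,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    mclust
biocViews: SingleCell, RNASeq, Clustering, GeneExpression, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
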