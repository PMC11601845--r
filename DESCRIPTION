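Package: nichescape
Title: Spatial Cellular Neighborhood Analysis for Multiplexed Tissue Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of CODEX-style multiplexed tissue imaging data at
    single-cell resolution: stochastic dilation of nuclear segmentation masks
    into whole-cell masks, inverse-hyperbolic-sine normalization and
    graph-based (PCA / k-nearest-neighbor / Leiden) phenotyping of per-cell
    marker intensities, discovery of cellular neighborhoods from spatial
    k-nearest-neighbor composition vectors via k-means with silhouette model
    selection, spatial statistics (average minimal inter-type distances,
    neighborhood-proportion cohort comparisons with Bonferroni correction,
    permutation-based cell-cell interaction enrichment), and combined z-score
    gene-signature scoring with median stratification and the associated
    group-level tests. Includes a synthetic-data module that generates
    planted-structure tissues, non-overlapping nuclear mask rasters and
    group-shifted expression matrices for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    cluster,
    S4Vectors,
    SummarizedExperiment,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    jsonlite,
    knitr,
    rmarkdown
biocViews: Spatial, SingleCell, Proteomics, Clustering, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
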