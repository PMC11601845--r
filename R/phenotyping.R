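#' Normalize per-cell marker intensities
#'
#' Applies the variance-stabilizing inverse hyperbolic sine transform
#' `x -> asinh(x / cofactor)` to every marker in every ROI, then
#' standardizes. With `scale = "both"` (default) values are z-scaled across
#' both cells and markers: first each marker is standardized across the
#' cells of its ROI (so ROI-level intensity shifts cannot act as batch
#' effects), then each cell's profile is standardized across markers. With
#' `scale = "marker"` only the per-marker stage is applied, leaving every
#' marker column with mean 0 and sd 1 within its ROI.
#'
#' @param x a [CodexExperiment-class] with an `"intensities"` assay.
#' @param cofactor positive asinh cofactor; the default 1 applies a bare
#'   `asinh`.
#' @param scale `"both"` (per-marker within ROI, then per-cell) or
#'   `"marker"` (per-marker within ROI only).
#' @param zeroVariance what to do with a marker that has zero variance
#'   within an ROI: `"error"` (default; the error names the marker) or
#'   `"zero"` (flag it and center it to 0, so it carries no signal).
#' @return `x` with a `"normalized"` assay added and provenance (cofactor,
#'   scaling mode, flagged markers) recorded in
#'   `metadata(x)$normalization`.
#' @examples
#' ce <- simulateTissue(tissueSimConfig(n_rois = 2, cells_per_roi = 100))
#' ce <- normalizeMarkers(ce)
#' assayNames(ce)
#' @export
normalizeMarkers <- function(x, cofactor = 1,
                             scale = c("both", "marker"),
                             zeroVariance = c("error", "zero")) {
    scale <- match.arg(scale)
    zeroVariance <- match.arg(zeroVariance)
    if (!is(x, "CodexExperiment")) stop("'x' must be a CodexExperiment")
    if (cofactor <= 0) stop("cofactor must be positive")
    raw <- assay(x, "intensities")
    if (any(!is.finite(raw)) || any(raw < 0)) {
        stop("intensities must be finite and non-negative")
    }
    a <- t(asinh(raw / cofactor))            # cells x markers
    roi <- roiIds(x)
    flagged <- character(0)
    for (r in unique(roi)) {
        sel <- roi == r
        z <- .zscoreColumns(a[sel, , drop = FALSE], onZeroVar =
                            if (zeroVariance == "error") "error" else "zero",
                            context = sprintf("in ROI '%s'", r))
        flagged <- union(flagged, attr(z, "flagged"))
        a[sel, ] <- z
    }
    if (scale == "both") {
        mu <- rowMeans(a)
        sdv <- apply(a, 1, sd)
        sdv[sdv == 0] <- 1                   # all-equal profile stays centred
        a <- (a - mu) / sdv
    }
    assay(x, "normalized") <- t(a)
    metadata(x)$normalization <- list(cofactor = cofactor, scale = scale,
                                      flagged_markers = flagged)
    x
}

#' Cluster cells into phenotypes (PCA / kNN graph / Leiden)
#'
#' Reduces the normalized marker matrix to `nPcs` principal components,
#' builds an exact Euclidean k-nearest-neighbor graph in PC space
#' (`graphK` neighbors, self excluded, ties broken by cell index, edges
#' symmetrized and unweighted) and partitions it with the Leiden community
#' detection algorithm at the given resolution (modularity objective by
#' default). Deterministic for a fixed seed.
#'
#' @param x a [CodexExperiment-class] already passed through
#'   [normalizeMarkers()].
#' @param nPcs number of principal components (default 20; capped at the
#'   number of markers, in which case PCA is a plain rotation).
#' @param graphK neighbors per cell in the similarity graph (default 30).
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param seed integer RNG seed for the Leiden refinement.
#' @param objective Leiden quality function, `"modularity"` (default) or
#'   `"CPM"`.
#' @param nIterations Leiden iterations.
#' @return `x` with integer cluster labels in `colData(x)$cluster` and the
#'   full parameter provenance in `metadata(x)$phenotyping`.
#' @examples
#' ce <- simulateTissue(tissueSimConfig(n_rois = 1, cells_per_roi = 400))
#' ce <- clusterCells(normalizeMarkers(ce), seed = 1)
#' table(clusterLabels(ce))
#' @export
clusterCells <- function(x, nPcs = 20, graphK = 30, resolution = 1.0,
                         seed = 1L, objective = c("modularity", "CPM"),
                         nIterations = 5) {
    objective <- match.arg(objective)
    if (!"normalized" %in% assayNames(x)) {
        stop("run normalizeMarkers() first: no 'normalized' assay found")
    }
    n <- ncol(x)
    if (n < graphK + 1) {
        stop("need at least graphK + 1 = ", graphK + 1, " cells, have ", n)
    }
    m <- t(assay(x, "normalized"))           # cells x markers
    nPcs <- min(nPcs, ncol(m), n - 1L)
    pcs <- prcomp(m, center = TRUE, scale. = FALSE)$x[, seq_len(nPcs),
                                                      drop = FALSE]
    knn <- .knnExact(pcs, graphK)
    el <- cbind(rep(seq_len(n), each = graphK), as.vector(t(knn$index)))
    gr <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    set.seed(seed)
    part <- igraph::cluster_leiden(gr, objective_function = objective,
                                   resolution = resolution,
                                   n_iterations = nIterations)
    labels <- as.integer(igraph::membership(part))
    colData(x)$cluster <- labels
    metadata(x)$phenotyping <- list(n_pcs = as.integer(nPcs),
                                    graph_k = as.integer(graphK),
                                    resolution = resolution,
                                    objective = objective, seed = seed,
                                    n_iterations = nIterations)
    x
}

#' Mean normalized expression profile of each phenotype cluster
#'
#' @param x a clustered [CodexExperiment-class] (see [clusterCells()]).
#' @param assay assay to average, default `"normalized"`.
#' @param by which label column to profile, `"cluster"` (default) or
#'   `"phenotype"`.
#' @return Matrix, one row per cluster, one column per marker; row `c` is
#'   the arithmetic mean profile of the cells in cluster `c`.
#' @export
profileClusters <- function(x, assay = "normalized",
                            by = c("cluster", "phenotype")) {
    by <- match.arg(by)
    labels <- colData(x)[[by]]
    if (is.null(labels)) stop("no '", by, "' labels found; cluster first")
    if (anyNA(labels)) stop("labels must cover every cell")
    m <- assay(x, assay)                     # markers x cells
    levs <- sort(unique(labels))
    prof <- t(vapply(levs, function(l) {
        rowMeans(m[, labels == l, drop = FALSE])
    }, numeric(nrow(m))))
    rownames(prof) <- as.character(levs)
    prof
}

#' Annotate phenotype clusters with biological names
#'
#' Maps the integer cluster labels assigned by [clusterCells()] to
#' user-chosen phenotype names (the manual-inspection step of a CODEX
#' analysis). The mapping must cover every cluster present.
#'
#' @param x a clustered [CodexExperiment-class].
#' @param mapping named character vector: `names(mapping)` are cluster
#'   labels (as characters), values are phenotype names. Several clusters
#'   may map to the same phenotype.
#' @return `x` with `colData(x)$phenotype` populated.
#' @export
annotateCells <- function(x, mapping) {
    cl <- clusterLabels(x)
    if (is.null(cl)) stop("no cluster labels; run clusterCells() first")
    uncovered <- setdiff(as.character(sort(unique(cl))), names(mapping))
    if (length(uncovered)) {
        stop("mapping does not cover cluster label(s): ",
             paste(uncovered, collapse = ", "))
    }
    phenotypes(x) <- unname(mapping[as.character(cl)])
    x
}
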