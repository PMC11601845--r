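#' CodexExperiment: per-cell marker intensities with spatial metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one column
#' per segmented cell and one row per protein marker. The `"intensities"`
#' assay stores raw (non-negative) fluorescence values;
#' [normalizeMarkers()] adds a `"normalized"` assay. Column metadata must
#' carry `roi_id` (region of interest), `x_um` and `y_um` (centroid in
#' microns); optional columns include `cohort`, `cluster`, `phenotype`,
#' `neighborhood`, and the simulator's ground-truth labels `true_type` and
#' `true_neighborhood`.
#'
#' @aliases CodexExperiment-class
#' @seealso [CodexExperiment()] for construction, [simulateTissue()] to
#'   generate one with planted structure.
#' @exportClass CodexExperiment
setClass("CodexExperiment", contains = "SummarizedExperiment")

setValidity("CodexExperiment", function(object) {
    cd <- colData(object)
    need <- c("roi_id", "x_um", "y_um")
    miss <- setdiff(need, colnames(cd))
    if (length(miss)) {
        return(sprintf("colData lacks required column(s): %s",
                       paste(miss, collapse = ", ")))
    }
    if (ncol(object) > 0) {
        xy <- cbind(cd$x_um, cd$y_um)
        if (!is.numeric(xy) || any(!is.finite(xy))) {
            return("x_um / y_um must be finite numeric centroids (microns)")
        }
        if (anyDuplicated(colnames(object))) {
            return("cell identifiers (colnames) must be unique")
        }
    }
    if (!"intensities" %in% assayNames(object)) {
        return("assay 'intensities' is required")
    }
    TRUE
})

#' LabelImage: integer-labelled segmentation raster
#'
#' A 2D raster of non-negative integers: pixel value 0 is background, value
#' v > 0 marks membership in mask v. Masks are pairwise disjoint by
#' construction (a pixel holds at most one label).
#'
#' @aliases LabelImage-class
#' @seealso [LabelImage()], [simulateLabelImage()], [dilateMasks()].
#' @exportClass LabelImage
setClass("LabelImage", representation(grid = "matrix"))

setValidity("LabelImage", function(object) {
    g <- object@grid
    if (!is.numeric(g)) return("grid must be a numeric/integer matrix")
    if (any(!is.finite(g))) return("grid must be finite")
    if (any(g < 0)) return("labels must be non-negative")
    if (any(g != round(g))) return("labels must be whole numbers")
    TRUE
})

#' SpatialGraph: per-ROI spatial k-nearest-neighbor relation
#'
#' For every cell, the ordered indices (into the cell vector) and Euclidean
#' distances (microns) of its `k` nearest neighbors within the same ROI.
#' Distances are non-decreasing along each row and a cell is never its own
#' neighbor.
#'
#' @aliases SpatialGraph-class
#' @seealso [buildKnnGraph()], [neighborComposition()],
#'   [interactionEnrichment()].
#' @exportClass SpatialGraph
setClass("SpatialGraph", representation(
    k = "integer",
    cellIds = "character",
    roi = "character",
    nnIndex = "matrix",
    nnDist = "matrix"
))

setValidity("SpatialGraph", function(object) {
    n <- length(object@cellIds)
    if (length(object@roi) != n) return("roi must have one entry per cell")
    if (!identical(dim(object@nnIndex), dim(object@nnDist))) {
        return("nnIndex and nnDist must have identical dimensions")
    }
    if (nrow(object@nnIndex) != n || ncol(object@nnIndex) != object@k) {
        return("nnIndex must be n cells x k")
    }
    if (n > 0) {
        if (any(object@nnIndex == seq_len(n))) {
            return("a cell may not be its own neighbor")
        }
        if (any(object@nnDist < 0)) return("distances must be non-negative")
    }
    TRUE
})

#' NeighborhoodModel: k-means cellular-neighborhood model
#'
#' The fitted k-means model over neighbor-composition proportion vectors:
#' the silhouette-selected number of neighborhoods `kCN`, the centroid
#' matrix (neighborhoods x phenotypes), the per-candidate-k mean silhouette
#' trace used for selection, the per-cell CN labels and the RNG seed.
#'
#' @aliases NeighborhoodModel-class
#' @seealso [discoverNeighborhoods()].
#' @exportClass NeighborhoodModel
setClass("NeighborhoodModel", representation(
    kCN = "integer",
    centers = "matrix",
    silhouetteTrace = "data.frame",
    labels = "integer",
    seed = "integer",
    params = "list"
))

setValidity("NeighborhoodModel", function(object) {
    if (nrow(object@centers) != object@kCN) {
        return("centers must have kCN rows")
    }
    tr <- object@silhouetteTrace
    if (!all(c("k", "silhouette") %in% colnames(tr))) {
        return("silhouetteTrace needs columns 'k' and 'silhouette'")
    }
    ok <- is.finite(tr$silhouette)
    if (any(ok) && {
        best <- max(tr$silhouette[ok])
        sel <- tr$silhouette[ok][match(object@kCN, tr$k[ok])]
        !isTRUE(all.equal(sel, best))
    }) {
        return("kCN must maximize the recorded silhouette trace")
    }
    if (length(object@labels) > 0 &&
        !all(object@labels %in% seq_len(object@kCN))) {
        return("labels must lie in 1..kCN")
    }
    TRUE
})
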