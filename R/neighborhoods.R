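#' Build the per-ROI spatial k-nearest-neighbor graph
#'
#' For every cell, finds its `k` closest cells (Euclidean distance on
#' centroids, in microns) within the same ROI. Neighbor lists are exact
#' (brute force), ordered by non-decreasing distance, with distance ties
#' broken by cell index, and never contain the cell itself or a cell from
#' another ROI.
#'
#' @param x a [CodexExperiment-class].
#' @param k neighbors per cell (default 10).
#' @return A [SpatialGraph-class].
#' @examples
#' ce <- simulateTissue(tissueSimConfig(n_rois = 2, cells_per_roi = 150))
#' g <- buildKnnGraph(ce, k = 10)
#' @export
buildKnnGraph <- function(x, k = 10) {
    if (!is(x, "CodexExperiment")) stop("'x' must be a CodexExperiment")
    k <- as.integer(k)
    if (k < 1) stop("k must be >= 1")
    coords <- spatialCoords(x)
    roi <- roiIds(x)
    n <- nrow(coords)
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    for (r in unique(roi)) {
        sel <- which(roi == r)
        if (length(sel) <= k) {
            stop("ROI '", r, "' has ", length(sel),
                 " cells; need more than k = ", k)
        }
        knn <- .knnExact(coords[sel, , drop = FALSE], k)
        idx[sel, ] <- matrix(sel[knn$index], nrow = length(sel))
        dst[sel, ] <- knn$dist
    }
    new("SpatialGraph", k = k, cellIds = colnames(x), roi = roi,
        nnIndex = idx, nnDist = dst)
}

#' @param x a [SpatialGraph-class].
#' @return `nnIndex()`/`nnDist()` return the n-cells-by-k neighbor index /
#'   distance matrices; `graphK()` the number of neighbors per cell.
#' @rdname SpatialGraph-accessors
#' @export
setMethod("nnIndex", "SpatialGraph", function(x) x@nnIndex)

#' @rdname SpatialGraph-accessors
#' @export
setMethod("nnDist", "SpatialGraph", function(x) x@nnDist)

#' @rdname SpatialGraph-accessors
#' @export
setMethod("graphK", "SpatialGraph", function(x) x@k)

setMethod("show", "SpatialGraph", function(object) {
    cat(sprintf("SpatialGraph: %d cells, k = %d, %d ROI(s)\n",
                length(object@cellIds), object@k,
                length(unique(object@roi))))
    invisible(object)
})

#' Neighbor-composition matrix
#'
#' For each cell, the proportion of each phenotype among its `k` spatial
#' neighbors (the index cell itself is excluded unless `includeSelf`).
#' Every row sums to 1.
#'
#' @param graph a [SpatialGraph-class].
#' @param phenotypes per-cell phenotype labels: a vector aligned with the
#'   graph's cells (or named by cell id). No missing values allowed.
#' @param includeSelf also count the index cell's own phenotype (then each
#'   row is a proportion over `k + 1` cells).
#' @return Numeric matrix, cells x phenotypes, rows summing to 1; row names
#'   are cell ids.
#' @export
neighborComposition <- function(graph, phenotypes, includeSelf = FALSE) {
    if (!is(graph, "SpatialGraph")) stop("'graph' must be a SpatialGraph")
    n <- length(graph@cellIds)
    if (!is.null(names(phenotypes))) {
        phenotypes <- phenotypes[graph@cellIds]
    }
    if (length(phenotypes) != n) {
        stop("need one phenotype per cell in the graph")
    }
    if (anyNA(phenotypes)) {
        stop("phenotype missing for ", sum(is.na(phenotypes)), " cell(s)")
    }
    ph <- factor(phenotypes)
    levs <- levels(ph)
    k <- graph@k
    nbPh <- matrix(as.integer(ph)[graph@nnIndex], nrow = n)
    denom <- k
    comp <- vapply(seq_along(levs), function(l) rowSums(nbPh == l),
                   numeric(n))
    if (includeSelf) {
        comp <- comp + outer(as.integer(ph), seq_along(levs), "==")
        denom <- k + 1
    }
    comp <- comp / denom
    dimnames(comp) <- list(graph@cellIds, levs)
    comp
}

#' Discover cellular neighborhoods by k-means with silhouette selection
#'
#' Fits k-means (multiple restarts) to the neighbor-composition proportion
#' vectors for every candidate number of neighborhoods, scores each
#' candidate by the mean silhouette width (Euclidean, on a seeded random
#' subsample of at most `silhouetteCap` rows for tractability) and returns
#' the model at the silhouette maximum. Candidates exceeding the number of
#' distinct composition rows are skipped with a warning.
#'
#' @param comp composition matrix from [neighborComposition()] (rows =
#'   cells; by the study's convention proportions, though a count matrix is
#'   accepted).
#' @param kCandidates integer vector of candidate neighborhood counts
#'   (default `2:10`).
#' @param seed integer RNG seed (restarts and silhouette subsample).
#' @param nstart k-means restarts per candidate (default 10, best inertia
#'   kept).
#' @param silhouetteCap maximum rows entering the silhouette computation;
#'   set to `Inf` for the full (quadratic-cost) computation.
#' @return A [NeighborhoodModel-class]; ties in the silhouette trace go to
#'   the smallest k.
#' @export
discoverNeighborhoods <- function(comp, kCandidates = 2:10, seed = 1L,
                                  nstart = 10, silhouetteCap = 5000) {
    comp <- as.matrix(comp)
    if (anyNA(comp)) stop("composition matrix contains missing values")
    nDistinct <- nrow(unique(comp))
    if (nDistinct < 2) {
        stop("degenerate composition matrix: all ", nrow(comp),
             " rows identical; no clustering with k >= 2 is possible")
    }
    kCandidates <- sort(unique(as.integer(kCandidates)))
    if (any(kCandidates < 2)) stop("candidate k must be >= 2")
    set.seed(seed)
    sub <- seq_len(nrow(comp))
    if (nrow(comp) > silhouetteCap) {
        sub <- sort(sample.int(nrow(comp), silhouetteCap))
    }
    dsub <- dist(comp[sub, , drop = FALSE])
    fits <- vector("list", length(kCandidates))
    sil <- rep(NA_real_, length(kCandidates))
    if (any(kCandidates > nDistinct)) {
        warning("skipping k = ",
                paste(kCandidates[kCandidates > nDistinct],
                      collapse = ", "),
                ": only ", nDistinct, " distinct composition rows")
    }
    for (i in seq_along(kCandidates)) {
        k <- kCandidates[i]
        if (k > nDistinct) next
        fit <- kmeans(comp, centers = k, nstart = nstart, iter.max = 100)
        cl <- fit$cluster[sub]
        if (length(unique(cl)) < 2) next     # silhouette undefined
        sw <- cluster::silhouette(cl, dsub)
        sil[i] <- mean(sw[, "sil_width"])
        fits[[i]] <- fit
    }
    if (all(is.na(sil))) {
        stop("no candidate k produced a valid silhouette score")
    }
    best <- which.max(replace(sil, is.na(sil), -Inf))  # ties -> smallest k
    fit <- fits[[best]]
    labels <- as.integer(fit$cluster)
    names(labels) <- rownames(comp)
    new("NeighborhoodModel",
        kCN = kCandidates[best],
        centers = fit$centers,
        silhouetteTrace = data.frame(k = kCandidates, silhouette = sil),
        labels = labels,
        seed = as.integer(seed),
        params = list(nstart = nstart, silhouetteCap = silhouetteCap,
                      kCandidates = kCandidates))
}

#' @param x a [NeighborhoodModel-class].
#' @return `chosenK()` gives the silhouette-selected number of
#'   neighborhoods; `cnCenters()` the centroid matrix; `cnLabels()` the
#'   per-cell CN labels (named integer vector); `silhouetteTrace()` the
#'   per-candidate-k mean silhouette data.frame.
#' @rdname NeighborhoodModel-accessors
#' @export
setMethod("chosenK", "NeighborhoodModel", function(x) x@kCN)

#' @rdname NeighborhoodModel-accessors
#' @export
setMethod("cnCenters", "NeighborhoodModel", function(x) x@centers)

#' @rdname NeighborhoodModel-accessors
#' @export
setMethod("cnLabels", "NeighborhoodModel", function(x) x@labels)

#' @rdname NeighborhoodModel-accessors
#' @export
setMethod("silhouetteTrace", "NeighborhoodModel",
          function(x) x@silhouetteTrace)

setMethod("show", "NeighborhoodModel", function(object) {
    cat(sprintf("NeighborhoodModel: %d cellular neighborhoods over %d cells\n",
                object@kCN, length(object@labels)))
    tr <- object@silhouetteTrace
    cat("  silhouette trace: ",
        paste(sprintf("k=%d:%.3f", tr$k, tr$silhouette), collapse = "  "),
        "\n", sep = "")
    invisible(object)
})

#' Per-ROI cellular-neighborhood proportions
#'
#' @param labels per-cell CN labels (e.g. `cnLabels(model)`), aligned with
#'   `roi` (or named by cell id with `roi` named the same way).
#' @param roi per-cell ROI identifiers, or a [CodexExperiment-class] whose
#'   cells match `labels`.
#' @return Matrix, one row per ROI and one column per CN; each row sums to
#'   1, with CNs absent from an ROI reported as 0.
#' @export
cnRoiProportions <- function(labels, roi) {
    if (is(roi, "CodexExperiment")) roi <- roiIds(roi)
    if (length(labels) != length(roi)) {
        stop("'labels' and 'roi' must have one entry per cell")
    }
    if (anyNA(labels)) stop("every cell must carry a CN label")
    tab <- table(roi = roi, cn = factor(labels))
    props <- tab / rowSums(tab)
    out <- matrix(as.numeric(props), nrow = nrow(tab),
                  dimnames = list(rownames(tab),
                                  paste0("CN", colnames(tab))))
    out
}
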