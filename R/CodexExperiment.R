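#' Construct a CodexExperiment
#'
#' Bundle a marker-by-cell intensity matrix with per-cell spatial metadata.
#'
#' @param intensities numeric matrix, markers x cells, raw non-negative
#'   fluorescence intensities. Row names are marker names, column names are
#'   unique cell identifiers.
#' @param cellData a `data.frame` or [S4Vectors::DataFrame] with one row per
#'   cell; must contain `roi_id`, `x_um`, `y_um` and may contain `cohort`
#'   and any label columns.
#' @param metadata optional list of experiment-level metadata.
#'
#' @return A [CodexExperiment-class] object.
#' @examples
#' m <- matrix(rlnorm(50), 5, 10,
#'             dimnames = list(paste0("M", 1:5), paste0("c", 1:10)))
#' cd <- data.frame(roi_id = "roi1", x_um = runif(10, 0, 100),
#'                  y_um = runif(10, 0, 100))
#' ce <- CodexExperiment(m, cd)
#' @export
CodexExperiment <- function(intensities, cellData, metadata = list()) {
    if (!is.matrix(intensities) || !is.numeric(intensities)) {
        stop("'intensities' must be a numeric matrix (markers x cells)")
    }
    if (any(!is.finite(intensities)) || any(intensities < 0)) {
        stop("intensities must be finite and non-negative")
    }
    cd <- as(cellData, "DataFrame")
    se <- SummarizedExperiment(
        assays = list(intensities = intensities),
        colData = cd, metadata = metadata
    )
    new("CodexExperiment", se)
}

#' Spatial centroids of all cells
#'
#' @param x a [CodexExperiment-class].
#' @return A two-column numeric matrix (`x_um`, `y_um`), one row per cell,
#'   in microns.
#' @rdname spatialCoords
#' @export
setMethod("spatialCoords", "CodexExperiment", function(x) {
    cd <- colData(x)
    m <- cbind(x_um = cd$x_um, y_um = cd$y_um)
    rownames(m) <- colnames(x)
    m
})

#' ROI membership of all cells
#'
#' @param x a [CodexExperiment-class].
#' @return Character vector of ROI identifiers, one per cell.
#' @rdname roiIds
#' @export
setMethod("roiIds", "CodexExperiment", function(x) {
    as.character(colData(x)$roi_id)
})

#' Cohort label of all cells
#'
#' @param x a [CodexExperiment-class].
#' @return Character vector of cohort labels (or `NULL` when unset).
#' @rdname cohorts
#' @export
setMethod("cohorts", "CodexExperiment", function(x) {
    co <- colData(x)$cohort
    if (is.null(co)) NULL else as.character(co)
})

#' Per-cell phenotype annotation
#'
#' @param x a [CodexExperiment-class].
#' @param value character/factor vector of phenotype names, one per cell.
#' @return `phenotypes()` returns the phenotype vector (or `NULL`).
#' @rdname phenotypes
#' @export
setMethod("phenotypes", "CodexExperiment", function(x) {
    ph <- colData(x)$phenotype
    if (is.null(ph)) NULL else as.character(ph)
})

#' @rdname phenotypes
#' @export
setMethod("phenotypes<-", "CodexExperiment", function(x, value) {
    if (length(value) != ncol(x)) stop("one phenotype per cell required")
    colData(x)$phenotype <- as.character(value)
    x
})

#' Per-cell phenotype cluster labels from [clusterCells()]
#'
#' @param x a [CodexExperiment-class].
#' @return Integer vector of cluster labels (or `NULL` before clustering).
#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "CodexExperiment", function(x) {
    cl <- colData(x)$cluster
    if (is.null(cl)) NULL else as.integer(cl)
})

#' Per-cell cellular-neighborhood annotation
#'
#' @param x a [CodexExperiment-class].
#' @param value vector of CN labels, one per cell.
#' @return `neighborhoods()` returns the CN label vector (or `NULL`).
#' @rdname neighborhoods
#' @export
setMethod("neighborhoods", "CodexExperiment", function(x) {
    nb <- colData(x)$neighborhood
    if (is.null(nb)) NULL else nb
})

#' @rdname neighborhoods
#' @export
setMethod("neighborhoods<-", "CodexExperiment", function(x, value) {
    if (length(value) != ncol(x)) stop("one neighborhood per cell required")
    colData(x)$neighborhood <- value
    x
})

setMethod("show", "CodexExperiment", function(object) {
    cat(sprintf("CodexExperiment: %d markers x %d cells\n",
                nrow(object), ncol(object)))
    cat(sprintf("  ROIs: %d | assays: %s\n",
                length(unique(roiIds(object))),
                paste(assayNames(object), collapse = ", ")))
    co <- cohorts(object)
    if (!is.null(co)) {
        tb <- table(co[!duplicated(roiIds(object))])
        cat(sprintf("  cohorts (ROIs): %s\n",
                    paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
    }
    extra <- intersect(c("cluster", "phenotype", "neighborhood",
                         "true_type", "true_neighborhood"),
                       colnames(colData(object)))
    if (length(extra)) {
        cat(sprintf("  cell labels: %s\n", paste(extra, collapse = ", ")))
    }
    invisible(object)
})
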