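#' Read and write cell tables as CSV
#'
#' The on-disk cell table has columns `cell_id`, `roi_id`, `cohort`,
#' `x_um`, `y_um`, any label columns present (`phenotype`,
#' `neighborhood`, `true_type`, `true_neighborhood`, `cluster`), then one
#' column per marker with the raw intensities.
#'
#' @param x a [CodexExperiment-class].
#' @param path CSV file path.
#' @return `readCellTable()` returns a [CodexExperiment-class];
#'   `writeCellTable()` invisibly returns `path`.
#' @rdname cellTableIO
#' @export
writeCellTable <- function(x, path) {
    cd <- as.data.frame(colData(x))
    keep <- intersect(c("roi_id", "cohort", "x_um", "y_um", "phenotype",
                        "neighborhood", "true_type", "true_neighborhood",
                        "cluster"), colnames(cd))
    df <- cbind(data.frame(cell_id = colnames(x),
                           stringsAsFactors = FALSE),
                cd[, keep, drop = FALSE],
                as.data.frame(t(assay(x, "intensities"))))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname cellTableIO
#' @export
readCellTable <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    meta <- intersect(c("cell_id", "roi_id", "cohort", "x_um", "y_um",
                        "phenotype", "neighborhood", "true_type",
                        "true_neighborhood", "cluster"), colnames(df))
    markers <- setdiff(colnames(df), meta)
    if (!all(c("cell_id", "roi_id", "x_um", "y_um") %in% meta)) {
        stop("cell table needs columns cell_id, roi_id, x_um, y_um")
    }
    if (!length(markers)) stop("no marker columns found in ", path)
    m <- t(as.matrix(df[, markers, drop = FALSE]))
    colnames(m) <- df$cell_id
    cd <- df[, setdiff(meta, "cell_id"), drop = FALSE]
    rownames(cd) <- df$cell_id
    CodexExperiment(m, cd)
}

#' Read and write label images
#'
#' TIFF files (`.tif`/`.tiff`) are written as single-channel 16-bit
#' grayscale (labels up to 65535); any other extension uses a plain
#' whitespace-delimited integer matrix.
#'
#' @param x a [LabelImage-class].
#' @param path output path (`.tif`, `.tiff` or text).
#' @return `readLabelImage()` returns a [LabelImage-class];
#'   `writeLabelImage()` invisibly returns `path`.
#' @rdname labelImageIO
#' @export
writeLabelImage <- function(x, path) {
    g <- labelGrid(x)
    if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        if (max(g) > 65535) stop("labels exceed 16-bit TIFF range")
        tiff::writeTIFF(g / 65535, path, bits.per.sample = 16)
    } else {
        write.table(g, path, row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' @rdname labelImageIO
#' @export
readLabelImage <- function(path) {
    if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        g <- round(tiff::readTIFF(path) * 65535)
    } else {
        g <- as.matrix(read.table(path))
        dimnames(g) <- NULL
    }
    LabelImage(g)
}

#' Read and write expression matrices as CSV
#'
#' On disk: one row per sample with columns `sample_id`, `group`, then one
#' column per gene.
#'
#' @param x a `SummarizedExperiment` (genes x samples) as produced by
#'   [simulateExpression()].
#' @param path CSV file path.
#' @return `readExpressionMatrix()` returns a `SummarizedExperiment`
#'   (genes x samples, assay `"exprs"`, `colData$group`);
#'   `writeExpressionMatrix()` invisibly returns `path`.
#' @rdname expressionIO
#' @export
writeExpressionMatrix <- function(x, path) {
    df <- cbind(data.frame(sample_id = colnames(x),
                           group = as.character(colData(x)$group),
                           stringsAsFactors = FALSE),
                as.data.frame(t(assay(x, 1))))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname expressionIO
#' @export
readExpressionMatrix <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% colnames(df))) {
        stop("expected columns 'sample_id' and 'group' in ", path)
    }
    genes <- setdiff(colnames(df), c("sample_id", "group"))
    m <- t(as.matrix(df[, genes, drop = FALSE]))
    colnames(m) <- df$sample_id
    SummarizedExperiment(
        assays = list(exprs = m),
        colData = DataFrame(group = df$group, row.names = df$sample_id)
    )
}
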