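#' Construct a LabelImage
#'
#' @param grid integer matrix; 0 = background, v > 0 = membership in mask v.
#' @return A [LabelImage-class] object. `labelGrid()` extracts the raster.
#' @examples
#' img <- LabelImage(matrix(c(0, 1, 1, 0, 0, 2), 2, 3))
#' labelGrid(img)
#' @rdname LabelImage
#' @export
LabelImage <- function(grid) {
    storage.mode(grid) <- "integer"
    new("LabelImage", grid = grid)
}

#' @param x a [LabelImage-class].
#' @rdname LabelImage
#' @export
setMethod("labelGrid", "LabelImage", function(x) x@grid)

setMethod("dim", "LabelImage", function(x) dim(x@grid))

setMethod("show", "LabelImage", function(object) {
    g <- object@grid
    labs <- setdiff(unique(as.vector(g)), 0L)
    cat(sprintf("LabelImage: %d x %d pixels, %d mask(s), %d assigned px\n",
                nrow(g), ncol(g), length(labs), sum(g > 0)))
    invisible(object)
})
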