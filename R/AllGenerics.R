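#' @rdname spatialCoords
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname roiIds
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname cohorts
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))

#' @rdname phenotypes
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname phenotypes
#' @export
setGeneric("phenotypes<-", function(x, value) standardGeneric("phenotypes<-"))

#' @rdname clusterLabels
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname neighborhoods
#' @export
setGeneric("neighborhoods", function(x) standardGeneric("neighborhoods"))

#' @rdname neighborhoods
#' @export
setGeneric("neighborhoods<-",
           function(x, value) standardGeneric("neighborhoods<-"))

#' @rdname LabelImage
#' @export
setGeneric("labelGrid", function(x) standardGeneric("labelGrid"))

#' @rdname SpatialGraph-accessors
#' @export
setGeneric("nnIndex", function(x) standardGeneric("nnIndex"))

#' @rdname SpatialGraph-accessors
#' @export
setGeneric("nnDist", function(x) standardGeneric("nnDist"))

#' @rdname SpatialGraph-accessors
#' @export
setGeneric("graphK", function(x) standardGeneric("graphK"))

#' @rdname NeighborhoodModel-accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname NeighborhoodModel-accessors
#' @export
setGeneric("cnCenters", function(x) standardGeneric("cnCenters"))

#' @rdname NeighborhoodModel-accessors
#' @export
setGeneric("cnLabels", function(x) standardGeneric("cnLabels"))

#' @rdname NeighborhoodModel-accessors
#' @export
setGeneric("silhouetteTrace", function(x) standardGeneric("silhouetteTrace"))
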