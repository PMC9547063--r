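#' @title Accessor generics
#' @description Accessors for the network, flow-state and result classes.
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("vesselTable", function(x) standardGeneric("vesselTable"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nVessels", function(x) standardGeneric("nVessels"))

#' @rdname accessors
#' @export
setGeneric("capillaryFraction", function(x)
    standardGeneric("capillaryFraction"))

#' @rdname accessors
#' @export
setGeneric("pressures", function(x) standardGeneric("pressures"))

#' @rdname accessors
#' @export
setGeneric("flows", function(x) standardGeneric("flows"))

#' @rdname accessors
#' @export
setGeneric("meanFlow", function(x) standardGeneric("meanFlow"))

#' @rdname accessors
#' @export
setGeneric("meanRbcFlux", function(x) standardGeneric("meanRbcFlux"))

#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname accessors
#' @export
setGeneric("affectedSet", function(x) standardGeneric("affectedSet"))
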