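#' @rdname seriesYears
#' @export
setGeneric("seriesYears", function(x) standardGeneric("seriesYears"))

#' @rdname legendOf
#' @export
setGeneric("legendOf", function(x) standardGeneric("legendOf"))

#' @rdname legendCodes
#' @export
setGeneric("legendCodes", function(x) standardGeneric("legendCodes"))

#' @rdname legendClasses
#' @export
setGeneric("legendClasses", function(x) standardGeneric("legendClasses"))

#' @rdname analysisClasses
#' @export
setGeneric("analysisClasses", function(x) standardGeneric("analysisClasses"))

#' @rdname seriesLabels
#' @export
setGeneric("seriesLabels", function(x) standardGeneric("seriesLabels"))

#' @rdname fractionsOf
#' @export
setGeneric("fractionsOf", function(x) standardGeneric("fractionsOf"))

#' @rdname validCounts
#' @export
setGeneric("validCounts", function(x) standardGeneric("validCounts"))

#' @rdname slopeLayer
#' @export
setGeneric("slopeLayer", function(x, class) standardGeneric("slopeLayer"))

#' @rdname pValueLayer
#' @export
setGeneric("pValueLayer", function(x, class) standardGeneric("pValueLayer"))

#' @rdname netAreaLayer
#' @export
setGeneric("netAreaLayer", function(x, class) standardGeneric("netAreaLayer"))

#' @rdname sdAreaLayer
#' @export
setGeneric("sdAreaLayer", function(x, class) standardGeneric("sdAreaLayer"))

#' @rdname significanceLayer
#' @export
setGeneric("significanceLayer", function(x, class) standardGeneric("significanceLayer"))

#' @rdname rawNetArea
#' @export
setGeneric("rawNetArea", function(x, class) standardGeneric("rawNetArea"))

#' @rdname designedSlopes
#' @export
setGeneric("designedSlopes", function(x) standardGeneric("designedSlopes"))

#' @rdname designedNetFraction
#' @export
setGeneric("designedNetFraction", function(x) standardGeneric("designedNetFraction"))
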