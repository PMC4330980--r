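#' @rdname genotypes
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname responses
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname doses
#' @export
setGeneric("doses", function(x) standardGeneric("doses"))

#' @rdname truthSpec
#' @export
setGeneric("truthSpec", function(x) standardGeneric("truthSpec"))

#' @rdname meanCurve
#' @export
setGeneric("meanCurve", function(x) standardGeneric("meanCurve"))

#' @rdname markerIds
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname ardSamples
#' @export
setGeneric("ardSamples", function(x) standardGeneric("ardSamples"))

#' @rdname acceptanceRate
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))

#' @rdname scanTable
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname selectedMarkers
#' @export
setGeneric("selectedMarkers", function(x) standardGeneric("selectedMarkers"))
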