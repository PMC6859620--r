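#' @rdname DecayFit-class
#' @param x a `DecayFit` object.
#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))
#' @rdname DecayFit-class
#' @export
setMethod("decayRate", "DecayFit", function(x) x@k)

#' @rdname DecayFit-class
#' @export
setGeneric("decayHalfLife", function(x) standardGeneric("decayHalfLife"))
#' @rdname DecayFit-class
#' @export
setMethod("decayHalfLife", "DecayFit", function(x) x@tHalf)

#' @rdname DecayFit-class
#' @export
setGeneric("fitRSquared", function(x) standardGeneric("fitRSquared"))
#' @rdname DecayFit-class
#' @export
setMethod("fitRSquared", "DecayFit", function(x) x@rSquared)
#' @rdname CalibrationCurve-class
#' @param x a `CalibrationCurve` object.
#' @export
setMethod("fitRSquared", "CalibrationCurve", function(x) x@rSquared)

#' @rdname CalibrationCurve-class
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))
#' @rdname CalibrationCurve-class
#' @export
setMethod("curveSlope", "CalibrationCurve", function(x) x@slope)

#' @rdname CalibrationCurve-class
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))
#' @rdname CalibrationCurve-class
#' @export
setMethod("curveIntercept", "CalibrationCurve", function(x) x@intercept)

#' @rdname EnrichmentResult-class
#' @param x an `EnrichmentResult` object.
#' @export
setGeneric("esScore", function(x) standardGeneric("esScore"))
#' @rdname EnrichmentResult-class
#' @export
setMethod("esScore", "EnrichmentResult", function(x) x@es)

#' @rdname EnrichmentResult-class
#' @export
setGeneric("nesScore", function(x) standardGeneric("nesScore"))
#' @rdname EnrichmentResult-class
#' @export
setMethod("nesScore", "EnrichmentResult", function(x) x@nes)

#' @rdname EnrichmentResult-class
#' @export
setGeneric("permPValue", function(x) standardGeneric("permPValue"))
#' @rdname EnrichmentResult-class
#' @export
setMethod("permPValue", "EnrichmentResult", function(x) x@pValue)
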