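#' @name accessors
#' @title Accessors for flyTurnover objects
#' @description Slot accessors for the S4 containers. Use these rather than
#'   `@` access; the slot layout is not part of the API.
#' @param x a flyTurnover object.
#' @return The corresponding component; see the class documentation.
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))
#' @rdname accessors
#' @export
setGeneric("cameraId", function(x) standardGeneric("cameraId"))
#' @rdname accessors
#' @export
setGeneric("vialId", function(x) standardGeneric("vialId"))
#' @rdname accessors
#' @export
setGeneric("assayDay", function(x) standardGeneric("assayDay"))
#' @rdname accessors
#' @export
setGeneric("totalFluorescence", function(x) standardGeneric("totalFluorescence"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setGeneric("days", function(x) standardGeneric("days"))
#' @rdname accessors
#' @export
setGeneric("vialMeans", function(x) standardGeneric("vialMeans"))
#' @rdname accessors
#' @export
setGeneric("groupMean", function(x) standardGeneric("groupMean"))
#' @rdname accessors
#' @export
setGeneric("groupSd", function(x) standardGeneric("groupSd"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("decaySlope", function(x) standardGeneric("decaySlope"))
#' @rdname accessors
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("slopeSe", function(x) standardGeneric("slopeSe"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("decayWindow", function(x) standardGeneric("decayWindow"))
#' @rdname accessors
#' @export
setGeneric("timeUnit", function(x) standardGeneric("timeUnit"))
#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' Quantify every frame of a stack
#'
#' Applies the per-frame threshold quantifier to each frame in order and
#' returns a [FluorescenceSeries-class] carrying the stack's identity.
#'
#' @param stack a [FrameStack-class].
#' @param config a [QuantConfig-class].
#' @return A [FluorescenceSeries-class] with one record per frame.
#' @seealso [quantifyFrame()]
#' @export
setGeneric("quantifyStack", function(stack, config) standardGeneric("quantifyStack"))

#' Trapezoidal area under a fluorescence time course
#'
#' Integrates the group-mean fluorescence over the full day grid with the
#' trapezoid rule; a measure of total reporter accumulation over the assay.
#'
#' @param x a [GroupTimecourse-class], or a numeric vector of time points.
#' @param values fluorescence values when `x` is a numeric time vector.
#' @return An [AUCResult-class].
#' @examples
#' computeAUC(c(0, 1, 2), c(0, 2, 0))  # area 2
#' @export
setGeneric("computeAUC", function(x, values) standardGeneric("computeAUC"))
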