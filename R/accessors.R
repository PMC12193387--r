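# Accessor methods and show() methods. Kept boring on purpose.

#' @rdname accessors
setMethod("frames", "FrameStack", function(x) x@frames)
#' @rdname accessors
setMethod("fps", "FrameStack", function(x) x@fps)
#' @rdname accessors
setMethod("cameraId", "FrameStack", function(x) x@cameraId)
#' @rdname accessors
setMethod("cameraId", "FluorescenceSeries", function(x) x@cameraId)
#' @rdname accessors
setMethod("vialId", "FrameStack", function(x) x@vialId)
#' @rdname accessors
setMethod("vialId", "FluorescenceSeries", function(x) x@vialId)
#' @rdname accessors
setMethod("assayDay", "FrameStack", function(x) x@day)
#' @rdname accessors
setMethod("assayDay", "FluorescenceSeries", function(x) x@day)
#' @rdname accessors
setMethod("totalFluorescence", "FluorescenceSeries",
          function(x) x@records$total_fluorescence)
#' @rdname accessors
setMethod("nObjects", "FluorescenceSeries", function(x) x@records$n_objects)
#' @rdname accessors
setMethod("days", "GroupTimecourse", function(x) x@days)
#' @rdname accessors
setMethod("vialMeans", "GroupTimecourse", function(x) x@vialMeans)
#' @rdname accessors
setMethod("groupMean", "GroupTimecourse", function(x) x@groupMean)
#' @rdname accessors
setMethod("groupSd", "GroupTimecourse", function(x) x@groupSd)
#' @rdname accessors
setMethod("groupLabel", "GroupTimecourse", function(x) x@group)
#' @rdname accessors
setMethod("decaySlope", "DecayFit", function(x) x@slope)
#' @rdname accessors
setMethod("halfLife", "DecayFit", function(x) x@halfLife)
#' @rdname accessors
setMethod("rSquared", "DecayFit", function(x) x@rSquared)
#' @rdname accessors
setMethod("slopeSe", "DecayFit", function(x) x@slopeSe)
#' @rdname accessors
setMethod("nPoints", "DecayFit", function(x) x@nPoints)
#' @rdname accessors
setMethod("decayWindow", "DecayFit", function(x) x@window)
#' @rdname accessors
setMethod("timeUnit", "DecayFit", function(x) x@timeUnit)
#' @rdname accessors
setMethod("auc", "AUCResult", function(x) x@auc)

#' Coerce a FluorescenceSeries to a data.frame
#'
#' @param x a [FluorescenceSeries-class].
#' @param ... ignored.
#' @return data.frame with frame_index, camera_id, vial_id, day,
#'   total_fluorescence, n_objects (the per-frame CSV schema).
#' @export
as.data.frame.FluorescenceSeries <- function(x, ...) {
    data.frame(frame_index = x@records$frame_index,
               camera_id = paste(x@cameraId, collapse = "+"),
               vial_id = x@vialId, day = x@day,
               total_fluorescence = x@records$total_fluorescence,
               n_objects = x@records$n_objects,
               stringsAsFactors = FALSE)
}

#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nVials, "vial(s) x", object@nCameras,
        "camera(s) x", object@nDays, "day(s),",
        object@nFramesPerDay, "frames/day @", object@fps, "fps\n")
    cat("  ", object@nFlies, " flies/vial, radius ", object@flyRadiusPx,
        " px, peak ", object@flyPeakIntensity, " AU on day ", object@peakDay,
        ", background ", object@backgroundLevel, " AU, noise sd ",
        object@noiseSd, " AU\n", sep = "")
    cat("  true half-life:", object@trueHalfLife, "days; seed:",
        object@seed, "\n")
})

#' @export
setMethod("show", "FrameStack", function(object) {
    d <- dim(object@frames[[1]])
    cat("FrameStack: camera ", object@cameraId, ", vial ", object@vialId,
        ", day ", object@day, "\n  ", length(object@frames), " frame(s) of ",
        d[1], "x", d[2], " px @ ", object@fps, " fps\n", sep = "")
})

#' @export
setMethod("show", "FluorescenceSeries", function(object) {
    tf <- object@records$total_fluorescence
    cat("FluorescenceSeries: camera(s) ",
        paste(object@cameraId, collapse = "+"), ", vial ", object@vialId,
        ", day ", object@day, "\n  ", nrow(object@records),
        " frame record(s); total fluorescence ", sep = "")
    if (length(tf)) cat(format(min(tf)), "-", format(max(tf)), "AU\n")
    else cat("(empty)\n")
})

#' @export
setMethod("show", "GroupTimecourse", function(object) {
    cat("GroupTimecourse '", object@group, "': ", nrow(object@vialMeans),
        " vial(s) x ", length(object@days), " day(s)\n", sep = "")
    print(data.frame(day = object@days, mean = object@groupMean,
                     sd = object@groupSd))
})

#' @export
setMethod("show", "DecayFit", function(object) {
    cat("DecayFit (ln F ~ time, ", object@nPoints, " points, window ",
        object@window[1], "-", object@window[2], "):\n", sep = "")
    cat("  slope: ", format(object@slope), " /", object@timeUnit,
        " (se ", format(object@slopeSe), "), r^2 ",
        format(object@rSquared), "\n", sep = "")
    if (is.na(object@halfLife))
        cat("  half-life: undefined (non-negative slope)\n")
    else
        cat("  half-life: ", format(round(object@halfLife, 2)), " ",
            object@timeUnit, "\n", sep = "")
})

#' @export
setMethod("show", "AUCResult", function(object) {
    cat("AUC (", object@method, "): ", format(object@auc), " over [",
        object@span[1], ", ", object@span[2], "]\n", sep = "")
})
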