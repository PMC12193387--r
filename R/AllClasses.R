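#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration for a synthetic video experiment
#'
#' Holds every parameter of the forward model used by
#' [simulateVideoExperiment()]: flies are uniform-intensity disks performing a
#' reflected Gaussian random walk inside a rectangular vial region, imaged by
#' two independent cameras, with the per-fly intensity following first-order
#' (exponential) decay across days after the expression peak.
#'
#' @slot nFlies flies per vial.
#' @slot flyRadiusPx disk radius in pixels.
#' @slot flyPeakIntensity per-pixel fly intensity at the peak day (AU).
#' @slot backgroundLevel background intensity (AU); must be below
#'   `flyPeakIntensity`.
#' @slot noiseSd per-pixel additive Gaussian noise SD (AU); frames are clipped
#'   at zero after noise so detector counts stay non-negative.
#' @slot frameShape integer (height, width) in pixels.
#' @slot roi vial region as (rowMin, rowMax, colMin, colMax), 0-based
#'   half-open; flies never leave it.
#' @slot nFramesPerDay frames recorded per day per camera.
#' @slot fps nominal frame rate (frames/second).
#' @slot nDays number of daily time points (day indices `0:(nDays-1)`).
#' @slot trueHalfLife programmed half-life in days.
#' @slot peakDay day index at which fly intensity is maximal.
#' @slot nVials replicate vials.
#' @slot nCameras synchronized cameras per vial (2 in the assay).
#' @slot stepSd random-walk step SD in pixels per frame.
#' @slot seed integer RNG seed; identical seed and config give bit-identical
#'   output.
#' @seealso [simConfig()] for the user constructor with assay defaults.
#' @export
setClass("SimConfig", representation(
    nFlies = "integer", flyRadiusPx = "integer", flyPeakIntensity = "numeric",
    backgroundLevel = "numeric", noiseSd = "numeric", frameShape = "integer",
    roi = "integer", nFramesPerDay = "integer", fps = "numeric",
    nDays = "integer", trueHalfLife = "numeric", peakDay = "integer",
    nVials = "integer", nCameras = "integer", stepSd = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@flyPeakIntensity <= object@backgroundLevel)
        msg <- c(msg, "flyPeakIntensity must exceed backgroundLevel")
    if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    counts <- c(object@nFlies, object@nFramesPerDay, object@nDays,
                object@nVials, object@nCameras, object@flyRadiusPx)
    if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
    if (object@trueHalfLife <= 0) msg <- c(msg, "trueHalfLife must be > 0")
    if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
    if (length(object@frameShape) != 2L || any(object@frameShape < 1L))
        msg <- c(msg, "frameShape must be two positive integers")
    if (object@peakDay < 0L || object@peakDay >= object@nDays)
        msg <- c(msg, "peakDay must lie in 0:(nDays-1)")
    r <- object@roi
    if (length(r) != 4L || r[1] < 0L || r[3] < 0L ||
        r[2] > object@frameShape[1] || r[4] > object@frameShape[2] ||
        r[2] <= r[1] || r[4] <= r[3])
        msg <- c(msg, "roi must be a non-empty rectangle inside the frame")
    if (length(msg)) msg else TRUE
})

#' Ordered single-camera frame stack
#'
#' The frames from one camera viewing one vial on one day: an ordered list of
#' same-shaped non-negative intensity matrices plus the nominal frame rate and
#' the stack's identity (camera, vial, day).
#'
#' @slot frames list of numeric matrices (AU), all the same shape.
#' @slot fps frames per second (> 0).
#' @slot cameraId,vialId labels.
#' @slot day time point in days.
#' @export
setClass("FrameStack", representation(
    frames = "list", fps = "numeric", cameraId = "character",
    vialId = "character", day = "numeric"))

setValidity("FrameStack", function(object) {
    msg <- character()
    if (!length(object@frames)) msg <- c(msg, "frames must be non-empty")
    if (length(object@frames)) {
        dims <- vapply(object@frames, dim, integer(2))
        if (!all(dims == dims[, 1])) msg <- c(msg, "all frames must share one shape")
        if (any(vapply(object@frames, function(f) any(f < 0), logical(1))))
            msg <- c(msg, "intensities must be >= 0")
    }
    if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
    if (length(msg)) msg else TRUE
})

#' Per-frame quantification configuration
#'
#' The detection parameters of the per-frame fly-fluorescence quantifier:
#' pixel threshold, region of interest, optional exclusion mask and minimum
#' blob size. Mirrors the threshold/ROI/mask triple a user would pick on
#' representative videos before batch analysis.
#'
#' @slot threshold pixel detection threshold (AU); comparison is strict
#'   (`intensity > threshold`).
#' @slot roi integer (rowMin, rowMax, colMin, colMax), 0-based half-open.
#' @slot mask optional binary matrix, same shape as the frames; nonzero pixels
#'   are excluded from detection.
#' @slot minBlobPx minimum 8-connected component size counted as a fly
#'   (default 1: pure threshold behaviour).
#' @seealso [quantConfig()], [quantifyFrame()]
#' @export
setClass("QuantConfig", representation(
    threshold = "numeric", roi = "integer", mask = "matrixOrNULL",
    minBlobPx = "integer"))

setValidity("QuantConfig", function(object) {
    msg <- character()
    if (object@threshold < 0) msg <- c(msg, "threshold must be >= 0")
    if (object@minBlobPx < 1L) msg <- c(msg, "minBlobPx must be >= 1")
    r <- object@roi
    if (length(r) != 4L || any(r < 0L) || r[2] <= r[1] || r[4] <= r[3])
        msg <- c(msg, "roi must be (rowMin, rowMax, colMin, colMax), non-empty, 0-based half-open")
    if (length(msg)) msg else TRUE
})

#' Per-frame fluorescence series
#'
#' One record per frame of total detected fly fluorescence, for a single
#' camera or for the merged dual-camera stream of one vial on one day.
#'
#' @slot records data.frame with columns `frame_index`, `total_fluorescence`
#'   and `n_objects`.
#' @slot cameraId one label per contributing camera.
#' @slot vialId,day identity of the stream.
#' @export
setClass("FluorescenceSeries", representation(
    records = "data.frame", cameraId = "character", vialId = "character",
    day = "numeric"))

setValidity("FluorescenceSeries", function(object) {
    msg <- character()
    need <- c("frame_index", "total_fluorescence", "n_objects")
    if (!all(need %in% names(object@records)))
        msg <- c(msg, sprintf("records must have columns %s",
                              paste(need, collapse = ", ")))
    else {
        if (any(object@records$total_fluorescence < 0))
            msg <- c(msg, "total_fluorescence must be >= 0")
        if (any(object@records$n_objects < 0))
            msg <- c(msg, "n_objects must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Group fluorescence time course
#'
#' Per-day mean fluorescence for each replicate vial of a group, with the
#' cross-vial mean and sample standard deviation — the content of the summary
#' table the pipeline writes.
#'
#' @slot group group label.
#' @slot days strictly increasing time points (days).
#' @slot vialMeans vials x days matrix of per-vial daily mean fluorescence
#'   (AU); `NA` marks a missing vial-day.
#' @slot groupMean per-day mean across vials (AU).
#' @slot groupSd per-day sample SD (n-1 denominator) across vials; `NA` where
#'   fewer than two vials contribute.
#' @export
setClass("GroupTimecourse", representation(
    group = "character", days = "numeric", vialMeans = "matrix",
    groupMean = "numeric", groupSd = "numeric"))

setValidity("GroupTimecourse", function(object) {
    msg <- character()
    nd <- length(object@days)
    if (nd && any(diff(object@days) <= 0))
        msg <- c(msg, "days must be strictly increasing")
    if (ncol(object@vialMeans) != nd)
        msg <- c(msg, "vialMeans must have one column per day")
    if (length(object@groupMean) != nd || length(object@groupSd) != nd)
        msg <- c(msg, "groupMean and groupSd must have one value per day")
    if (length(msg)) msg else TRUE
})

#' Log-linear decay fit
#'
#' Ordinary least-squares fit of ln(fluorescence) on time over the
#' peak-to-minimum window, with the half-life derived from the slope as
#' t1/2 = ln 2 / |slope|.
#'
#' @slot slope,intercept coefficients of ln F = intercept + slope * t.
#' @slot halfLife ln 2 / |slope| in `timeUnit`; `NA` when the slope is
#'   non-negative (no decay).
#' @slot rSquared,slopeSe fit diagnostics (slopeSe is `NA` with fewer than 3
#'   points).
#' @slot nPoints points used after dropping non-positive values.
#' @slot window (peak index, minimum index), 1-based, into the fitted series.
#' @slot timeUnit `"days"` or `"minutes"`; carried, never converted silently.
#' @export
setClass("DecayFit", representation(
    slope = "numeric", intercept = "numeric", halfLife = "numeric",
    rSquared = "numeric", slopeSe = "numeric", nPoints = "integer",
    window = "integer", timeUnit = "character"))

setValidity("DecayFit", function(object) {
    msg <- character()
    if (!is.na(object@halfLife)) {
        if (object@slope >= 0)
            msg <- c(msg, "halfLife must be NA when slope >= 0")
        else if (abs(object@halfLife * abs(object@slope) - log(2)) > 1e-12)
            msg <- c(msg, "halfLife * |slope| must equal ln 2")
    }
    if (length(msg)) msg else TRUE
})

#' Area under the fluorescence curve
#'
#' Trapezoidal integral of the group-mean fluorescence over the assay period;
#' a proxy for total reporter accumulation.
#'
#' @slot auc integral in AU x time-units.
#' @slot span (first, last) time point integrated.
#' @slot method integration rule label.
#' @export
setClass("AUCResult", representation(
    auc = "numeric", span = "numeric", method = "character"))

setValidity("AUCResult", function(object) {
    if (length(object@span) != 2L) "span must be (first, last)" else TRUE
})
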