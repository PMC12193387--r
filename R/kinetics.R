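#' Locate the peak-to-minimum decay window
#'
#' Half-life is estimated over the segment from the expression peak to the
#' subsequent minimum. The peak is the global maximum of the group mean
#' (earliest on ties); the minimum is the global minimum over points strictly
#' after the peak (earliest on ties). Interior bumps between the two are kept
#' — no monotonicity pruning — matching a plain regression over the chosen
#' range.
#'
#' @param x a [GroupTimecourse-class] or a numeric vector of (group-mean)
#'   fluorescence values.
#' @return Integer `c(peak, minimum)` of 1-based indices into the series.
#' @examples
#' findDecayWindow(c(1, 5, 3, 2, 1))  # c(2, 5)
#' @export
findDecayWindow <- function(x) {
    m <- if (is(x, "GroupTimecourse")) groupMean(x) else as.numeric(x)
    if (length(m) < 3L) stop("need at least 3 time points")
    peak <- which.max(m)
    if (peak == length(m))
        stop("no decay window: the peak is the last time point")
    minimum <- peak + which.min(m[(peak + 1L):length(m)])
    c(peak = peak, minimum = as.integer(minimum))
}

#' Convert a log-linear decay slope to a half-life
#'
#' Under first-order decay, ln F(t) = ln F(0) + b t with b < 0, and the
#' half-life is t1/2 = ln 2 / |b|, in the time unit of the slope.
#'
#' @param slope slope of ln(fluorescence) versus time (must be negative).
#' @return Half-life in the slope's time unit.
#' @examples
#' halfLifeFromSlope(-0.2558)  # 2.71 days at 2 d.p.
#' halfLifeFromSlope(-log(2))  # 1
#' @export
halfLifeFromSlope <- function(slope) {
    if (!is.finite(slope) || slope >= 0)
        stop("half-life is defined only for a negative decay slope (got ",
             format(slope), ")")
    log(2) / abs(slope)
}

#' Fit log-linear decay and estimate half-life
#'
#' Ordinary least squares of ln(fluorescence) on time over the decay window.
#' Non-positive values cannot be log-transformed and are dropped with a
#' warning (never offset: an epsilon shift would bias the slope). A
#' non-negative fitted slope yields a fit with an undefined (`NA`) half-life
#' rather than a fabricated large number.
#'
#' @param times time points (days or minutes).
#' @param values fluorescence values (AU), same length.
#' @param window optional `c(first, last)` 1-based index range to fit
#'   (e.g. from [findDecayWindow()]); default: all points.
#' @param timeUnit `"days"` or `"minutes"`, carried into the result.
#' @return A [DecayFit-class].
#' @examples
#' fitDecay(0:3, c(8, 4, 2, 1))  # slope -ln 2, half-life 1, r^2 = 1
#' @export
fitDecay <- function(times, values, window = NULL, timeUnit = "days") {
    stopifnot(length(times) == length(values))
    if (is.null(window)) window <- c(1L, length(times))
    idx <- window[1]:window[2]
    t <- times[idx]; v <- values[idx]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
        warning(sum(bad), " non-positive/missing value(s) dropped before ",
                "the log transform")
        t <- t[!bad]; v <- v[!bad]
    }
    if (length(v) < 2L)
        stop("fewer than 2 usable points in the decay window")
    fit <- stats::lm(log(v) ~ t)
    cf <- stats::coef(fit)
    slope <- unname(cf[2]); intercept <- unname(cf[1])
    sm <- suppressWarnings(summary(fit))
    se <- if (length(v) >= 3L) sm$coefficients[2, 2] else NA_real_
    r2 <- sm$r.squared
    hl <- if (is.finite(slope) && slope < 0) log(2) / abs(slope) else NA_real_
    if (is.na(hl))
        warning("non-negative slope: half-life undefined for this window")
    new("DecayFit", slope = slope, intercept = intercept, halfLife = hl,
        rSquared = r2, slopeSe = se, nPoints = length(v),
        window = as.integer(window), timeUnit = timeUnit)
}

#' Fit decay on a group time course
#'
#' Convenience wrapper: finds the peak-to-minimum window of the group mean
#' with [findDecayWindow()] and fits [fitDecay()] over it. By default the
#' fit uses the group means (per-vial fits showed no advantage in the assay);
#' `perVial = TRUE` returns one fit per vial over the group-level window.
#'
#' @param tc a [GroupTimecourse-class].
#' @param perVial fit each vial separately instead of the group mean.
#' @param timeUnit time unit label.
#' @return A [DecayFit-class], or a named list of them when `perVial = TRUE`.
#' @export
fitTimecourse <- function(tc, perVial = FALSE, timeUnit = "days") {
    stopifnot(is(tc, "GroupTimecourse"))
    win <- findDecayWindow(tc)
    if (!perVial)
        return(fitDecay(tc@days, tc@groupMean, window = win,
                        timeUnit = timeUnit))
    fits <- lapply(seq_len(nrow(tc@vialMeans)), function(v)
        fitDecay(tc@days, tc@vialMeans[v, ], window = win,
                 timeUnit = timeUnit))
    names(fits) <- rownames(tc@vialMeans)
    fits
}

#' Windowed ln-fluorescence points of a group
#'
#' The (time, ln fluorescence) points inside the group's peak-to-minimum
#' window — exactly the points [fitTimecourse()] regresses, and the input
#' unit for the slope-comparison ANCOVA, so the tested slopes are the
#' reported slopes.
#'
#' @param tc a [GroupTimecourse-class].
#' @return data.frame with `time` and `ln_fluorescence` (non-positive means
#'   dropped).
#' @export
windowedLnPoints <- function(tc) {
    stopifnot(is(tc, "GroupTimecourse"))
    win <- findDecayWindow(tc)
    idx <- win[1]:win[2]
    t <- tc@days[idx]; v <- tc@groupMean[idx]
    keep <- is.finite(v) & v > 0
    data.frame(time = t[keep], ln_fluorescence = log(v[keep]))
}

#' @describeIn computeAUC AUC of the group-mean fluorescence of a time course.
setMethod("computeAUC", signature("GroupTimecourse", "missing"),
    function(x, values) computeAUC(x@days, x@groupMean))

#' @describeIn computeAUC AUC of an explicit (times, values) series.
setMethod("computeAUC", signature("numeric", "numeric"),
    function(x, values) {
        if (length(x) < 2L) stop("need at least 2 time points")
        if (any(diff(x) <= 0)) stop("time points must be strictly increasing")
        if (length(x) != length(values)) stop("times and values differ in length")
        new("AUCResult", auc = pracma::trapz(x, values),
            span = c(x[1], x[length(x)]), method = "trapezoid")
    })

#' Fold change between two areas under the curve
#'
#' Ratio of total reporter accumulation, treated over control.
#'
#' @param treated,control [AUCResult-class] objects.
#' @return `auc(treated) / auc(control)`.
#' @export
aucFoldChange <- function(treated, control) {
    stopifnot(is(treated, "AUCResult"), is(control, "AUCResult"))
    if (control@auc == 0) stop("control AUC is zero: fold change undefined")
    treated@auc / control@auc
}
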