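#' Merge the two synchronized camera streams
#'
#' The two cameras view the same vial from different sides; their per-frame
#' totals are summed frame-by-frame, and merged frames whose combined total
#' is at or below `signalThreshold` are dropped (the sub-threshold filter:
#' frames where the flies were poorly visible carry no usable signal).
#'
#' @param seriesA,seriesB [FluorescenceSeries-class] objects of equal length
#'   with matching frame indices, vial and day.
#' @param signalThreshold combined-total threshold (AU); frames with merged
#'   total `<=` this value are removed.
#' @return A merged, filtered [FluorescenceSeries-class]. Object counts are
#'   summed across cameras (the views are not registered, so counts are not
#'   de-duplicated).
#' @examples
#' # totals 10,0,5 on each camera, threshold 4 -> merged 20, 10
#' @export
mergeCameras <- function(seriesA, seriesB, signalThreshold = 0) {
    stopifnot(is(seriesA, "FluorescenceSeries"),
              is(seriesB, "FluorescenceSeries"))
    a <- seriesA@records; b <- seriesB@records
    if (nrow(a) != nrow(b))
        stop("camera streams are not synchronized: ", nrow(a), " vs ",
             nrow(b), " frames")
    if (!all(a$frame_index == b$frame_index))
        stop("camera streams are not synchronized: frame indices differ")
    if (!identical(seriesA@vialId, seriesB@vialId) ||
        !identical(seriesA@day, seriesB@day))
        stop("camera streams disagree on vial/day identity")
    merged <- data.frame(
        frame_index = a$frame_index,
        total_fluorescence = a$total_fluorescence + b$total_fluorescence,
        n_objects = a$n_objects + b$n_objects)
    dropped <- merged$total_fluorescence <= signalThreshold
    if (any(dropped))
        message(sum(dropped), " of ", nrow(merged),
                " frame(s) below signal threshold dropped (vial ",
                seriesA@vialId, ", day ", seriesA@day, ")")
    new("FluorescenceSeries", records = merged[!dropped, , drop = FALSE],
        cameraId = c(seriesA@cameraId, seriesB@cameraId),
        vialId = seriesA@vialId, day = seriesA@day)
}

#' Daily fluorescence value for one vial
#'
#' The vial's value at a time point is the arithmetic mean of the surviving
#' merged per-frame totals.
#'
#' @param merged a merged [FluorescenceSeries-class].
#' @return The mean total fluorescence (AU), or `NA` with a warning when
#'   every frame was filtered out ("no signal" is distinct from zero signal
#'   and is excluded from fitting rather than imputed).
#' @export
vialDayValue <- function(merged) {
    stopifnot(is(merged, "FluorescenceSeries"))
    if (!nrow(merged@records)) {
        warning("no signal: all frames filtered out for vial ",
                merged@vialId, ", day ", merged@day)
        return(NA_real_)
    }
    mean(merged@records$total_fluorescence)
}

# Assemble a GroupTimecourse from a vials x days matrix.
groupTimecourseFromMatrix <- function(vm, days, group) {
    gm <- apply(vm, 2, function(x) mean(x, na.rm = TRUE))
    gs <- apply(vm, 2, function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2L) NA_real_ else stats::sd(x)
    })
    gm[is.nan(gm)] <- NA_real_
    new("GroupTimecourse", group = as.character(group),
        days = as.numeric(days), vialMeans = vm,
        groupMean = unname(gm), groupSd = unname(gs))
}

#' Aggregate per-vial daily values into a group time course
#'
#' Computes, for each day, the mean and sample standard deviation (n-1
#' denominator) of the per-vial values — the group time course the decay fit
#' operates on.
#'
#' @param vialValues data.frame with columns `vial_id`, `day`, `value`
#'   (one row per vial-day; `NA` values mark missing vial-days), or a
#'   vials x days matrix with vial ids as rownames.
#' @param group group label.
#' @param days day grid when `vialValues` is a matrix (defaults to its
#'   column names or 0-based indices).
#' @return A [GroupTimecourse-class]. Days observed in fewer than two vials
#'   get `NA` standard deviation; missing vial-days are flagged with a
#'   warning.
#' @examples
#' df <- data.frame(vial_id = rep(c("v1", "v2"), each = 2),
#'                  day = rep(0:1, 2), value = c(2, 1, 4, 3))
#' groupMean(aggregateGroup(df, "control"))  # 3, 2
#' @export
aggregateGroup <- function(vialValues, group, days = NULL) {
    if (is.matrix(vialValues)) {
        vm <- vialValues
        if (is.null(days))
            days <- if (!is.null(colnames(vm))) as.numeric(colnames(vm))
                    else seq_len(ncol(vm)) - 1
    } else {
        need <- c("vial_id", "day", "value")
        if (!all(need %in% names(vialValues)))
            stop("vialValues needs columns vial_id, day, value")
        if (!nrow(vialValues)) stop("no vials to aggregate")
        days <- sort(unique(vialValues$day))
        vials <- unique(vialValues$vial_id)
        vm <- matrix(NA_real_, length(vials), length(days),
                     dimnames = list(vials, days))
        vm[cbind(match(vialValues$vial_id, vials),
                 match(vialValues$day, days))] <- vialValues$value
    }
    if (!nrow(vm)) stop("no vials to aggregate")
    if (anyNA(vm))
        warning("missing vial-day values in group '", group, "': ",
                sum(is.na(vm)), " of ", length(vm))
    groupTimecourseFromMatrix(vm, days, group)
}

#' Write / read the group summary table
#'
#' The summary CSV mirrors the assay's reporting format: one row per day with
#' the per-vial daily means, the cross-vial mean and the sample SD. Numbers
#' are written with 17 significant digits so a read-back reproduces the
#' object exactly.
#'
#' @param tc a [GroupTimecourse-class].
#' @param path CSV path.
#' @return `writeSummaryCsv` returns `path` invisibly; `readSummaryCsv`
#'   returns the [GroupTimecourse-class].
#' @export
writeSummaryCsv <- function(tc, path) {
    stopifnot(is(tc, "GroupTimecourse"))
    vm <- t(tc@vialMeans)
    colnames(vm) <- rownames(tc@vialMeans)
    df <- data.frame(group = tc@group, day = tc@days, vm,
                     group_mean = tc@groupMean, group_sd = tc@groupSd,
                     check.names = FALSE)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x)
        ifelse(is.na(x), "NA", sprintf("%.17g", x)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSummaryCsv
#' @export
readSummaryCsv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    fixed <- c("group", "day", "group_mean", "group_sd")
    vcols <- setdiff(names(df), fixed)
    vm <- t(as.matrix(df[vcols]))
    colnames(vm) <- NULL
    new("GroupTimecourse", group = as.character(df$group[1]),
        days = as.numeric(df$day), vialMeans = vm,
        groupMean = as.numeric(df$group_mean),
        groupSd = as.numeric(df$group_sd))
}

#' Write / read the per-frame fluorescence CSV
#'
#' One row per frame: `frame_index`, `camera_id`, `vial_id`, `day`,
#' `total_fluorescence`, `n_objects` — the quantifier's output format.
#'
#' @param series a [FluorescenceSeries-class].
#' @param path CSV path.
#' @return `writeSeriesCsv` returns `path` invisibly; `readSeriesCsv`
#'   returns the [FluorescenceSeries-class].
#' @export
writeSeriesCsv <- function(series, path) {
    df <- as.data.frame(series)
    df$total_fluorescence <- sprintf("%.17g", df$total_fluorescence)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSeriesCsv
#' @export
readSeriesCsv <- function(path) {
    df <- utils::read.csv(path)
    new("FluorescenceSeries",
        records = data.frame(frame_index = df$frame_index,
                             total_fluorescence =
                                 as.numeric(df$total_fluorescence),
                             n_objects = df$n_objects),
        cameraId = strsplit(as.character(df$camera_id[1]), "+",
                            fixed = TRUE)[[1]],
        vialId = as.character(df$vial_id[1]), day = as.numeric(df$day[1]))
}
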