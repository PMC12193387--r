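# Pipeline composition: quantify -> merge -> aggregate -> fit -> compare,
# driven by a single configuration (the batch-file replacement).

configError <- function(...) {
    stop(structure(class = c("configError", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}
dataError <- function(...) {
    stop(structure(class = c("dataError", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

#' Load and validate a pipeline configuration
#'
#' The configuration is one human-readable YAML file; it replaces the
#' hand-edited batch file of the original workflow. Structure:
#' \preformatted{
#' quant:
#'   threshold: 2000        # pixel detection threshold (AU)
#'   roi: [2, 62, 2, 62]    # rowMin, rowMax, colMin, colMax (0-based, half-open)
#'   mask: null             # optional mask image path
#'   min_blob_px: 1
#' signal_threshold: 0      # merged per-frame total filter (AU)
#' time_unit: days
#' output_dir: results
#' groups:
#'   control: {data_dir: sim/control}
#'   treated: {data_dir: sim/treated}
#' }
#' Every referenced path is checked up front so a bad configuration fails
#' before any computation.
#'
#' @param config YAML path or an equivalent named list.
#' @return The validated configuration list, with `quant` replaced by a
#'   [QuantConfig-class] and masks loaded.
#' @export
loadPipelineConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) configError("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    need <- c("quant", "groups", "output_dir")
    miss <- setdiff(need, names(config))
    if (length(miss))
        configError("config is missing: ", paste(miss, collapse = ", "))
    q <- config$quant
    if (is.null(q$threshold) || is.null(q$roi) || length(q$roi) != 4L)
        configError("quant needs a threshold and a 4-element roi")
    mask <- NULL
    if (!is.null(q$mask)) {
        if (!file.exists(q$mask))
            configError("mask file not found: ", q$mask)
        mask <- readMask(q$mask)
    }
    config$quant <- quantConfig(q$threshold, unlist(q$roi), mask = mask,
                                minBlobPx = q$min_blob_px %||% 1L)
    if (!length(config$groups)) configError("no groups configured")
    if (anyDuplicated(names(config$groups)))
        configError("group labels must be unique")
    for (g in names(config$groups)) {
        dd <- config$groups[[g]]$data_dir
        if (is.null(dd) || !dir.exists(dd))
            configError("group '", g, "': data_dir missing or not found")
        if (!file.exists(file.path(dd, "manifest.csv")))
            configError("group '", g, "': no manifest.csv in ", dd)
    }
    config$signal_threshold <- config$signal_threshold %||% 0
    config$time_unit <- config$time_unit %||% "days"
    config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quantify, merge and aggregate one group's image data into a timecourse.
processGroup <- function(groupDir, group, quant, signalThreshold) {
    manifest <- readManifest(groupDir)
    vials <- unique(manifest$vial_id)
    dayGrid <- sort(unique(manifest$day))
    cams <- sort(unique(manifest$camera_id))
    rows <- list()
    perFrame <- list()
    for (v in vials) for (d in dayGrid) {
        streams <- lapply(cams, function(cam)
            quantifyStack(readFrameStack(groupDir, cam, v, d,
                                         manifest = manifest), quant))
        merged <- if (length(streams) == 1L) streams[[1]]
                  else Reduce(function(a, b)
                      mergeCameras(a, b, signalThreshold), streams)
        perFrame[[length(perFrame) + 1L]] <- as.data.frame(merged)
        rows[[length(rows) + 1L]] <- data.frame(
            vial_id = v, day = d, value = suppressWarnings(vialDayValue(merged)))
    }
    list(timecourse = aggregateGroup(do.call(rbind, rows), group),
         perFrame = do.call(rbind, perFrame))
}

#' Run the full turnover pipeline
#'
#' Executes quantify, merge, aggregate, fit and compare over every
#' configured group, writing all intermediate and final CSVs under the
#' configured output directory: per-frame merged fluorescence
#' (`frames_<group>.csv`), the group summary (`summary_<group>.csv`), the
#' decay-fit report (`fit_report.csv`), the AUC report (`auc_report.csv`),
#' the group-comparison statistics (`stats_report.csv`, when >= 2 groups)
#' and a run log recording versions and the configuration checksum.
#'
#' @param config YAML path or list (see [loadPipelineConfig()]).
#' @return Invisibly, a list with `timecourses`, `fits`, `aucs`, `ancova`
#'   (or NULL), `peakTest` (or NULL) and `outputDir`.
#' @export
runPipeline <- function(config) {
    configPath <- if (is.character(config)) config else NULL
    config <- loadPipelineConfig(config)
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    tcs <- list(); fits <- list(); aucs <- list()
    for (g in names(config$groups)) {
        res <- withCallingHandlers(
            tryCatch(processGroup(config$groups[[g]]$data_dir, g,
                                  config$quant, config$signal_threshold),
                     error = function(e) dataError("group '", g, "' (quantify/aggregate): ",
                                                   conditionMessage(e))),
            warning = function(w) {
                message("[", g, "] warning: ", conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        tcs[[g]] <- res$timecourse
        utils::write.csv(res$perFrame,
                         file.path(out, paste0("frames_", g, ".csv")),
                         row.names = FALSE, quote = FALSE)
        writeSummaryCsv(res$timecourse,
                        file.path(out, paste0("summary_", g, ".csv")))
        fits[[g]] <- tryCatch(
            fitTimecourse(res$timecourse, timeUnit = config$time_unit),
            error = function(e) dataError("group '", g, "' (fit): ",
                                          conditionMessage(e)))
        aucs[[g]] <- computeAUC(res$timecourse)
    }
    fitReport <- do.call(rbind, lapply(names(fits), function(g) {
        f <- fits[[g]]
        data.frame(group = g, slope = f@slope, slope_se = f@slopeSe,
                   half_life = f@halfLife, r_squared = f@rSquared,
                   n_points = f@nPoints, window_peak = f@window[1],
                   window_min = f@window[2], time_unit = f@timeUnit)
    }))
    utils::write.csv(fitReport, file.path(out, "fit_report.csv"),
                     row.names = FALSE, quote = FALSE)
    aucReport <- do.call(rbind, lapply(names(aucs), function(g)
        data.frame(group = g, auc = aucs[[g]]@auc,
                   span_first = aucs[[g]]@span[1],
                   span_last = aucs[[g]]@span[2])))
    utils::write.csv(aucReport, file.path(out, "auc_report.csv"),
                     row.names = FALSE, quote = FALSE)
    ancova <- NULL; peakTest <- NULL
    if (length(tcs) >= 2L) {
        ancova <- tryCatch(
            compareSlopesAncova(lapply(tcs, windowedLnPoints)),
            error = function(e) dataError("ancova: ", conditionMessage(e)))
        g12 <- names(tcs)[1:2]
        peakTest <- tryCatch(
            comparePeaks(peakVialValues(tcs[[g12[1]]]),
                         peakVialValues(tcs[[g12[2]]])),
            error = function(e) NULL)
        stats <- data.frame(
            comparison = "equal decay slopes (all groups)",
            test = "ANCOVA time x group interaction F",
            statistic = ancova$interactionF, df1 = ancova$df[1],
            df2 = ancova$df[2], p_value = ancova$pValue,
            note = paste0(ancova$nComparisons, " pairwise comparison(s); ",
                          "no multiplicity correction applied"))
        if (!is.null(peakTest))
            stats <- rbind(stats, data.frame(
                comparison = paste0("peak level: ", g12[1], " vs ", g12[2]),
                test = "Welch two-sample t", statistic = peakTest$statistic,
                df1 = peakTest$parameter, df2 = NA,
                p_value = peakTest$p.value, note = ""))
        utils::write.csv(stats, file.path(out, "stats_report.csv"),
                         row.names = FALSE, quote = FALSE)
    }
    writeLines(c(
        paste0("flyTurnover ", as.character(utils::packageVersion("flyTurnover"))),
        paste0("R ", R.version.string),
        paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
        paste0("config checksum: ",
               if (!is.null(configPath)) unname(tools::md5sum(configPath))
               else "(in-memory config)"),
        paste0("groups: ", paste(names(config$groups), collapse = ", "))),
        file.path(out, "run_log.txt"))
    invisible(list(timecourses = tcs, fits = fits, aucs = aucs,
                   ancova = ancova, peakTest = peakTest, outputDir = out))
}
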