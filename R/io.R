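# Image-sequence storage. Frames are written as 16-bit grayscale TIFF image
# sequences (one directory per day per camera) with a manifest CSV, rather
# than as video: codecs are lossy and nondeterministic, image sequences
# round-trip exactly. Intensities are stored as 16-bit counts, so AU values
# must lie in [0, 65535]; writing rounds to the nearest count.

tiffScale <- 65535

#' Write a simulated experiment as image sequences
#'
#' Writes every frame as 16-bit grayscale TIFF under
#' `dir/dayDD/camC/vialV_frameFFFF.tif`, a `manifest.csv` (columns
#' `filename`, `frame_index`, `camera_id`, `vial_id`, `day`, `fps`) and a
#' `ground_truth.csv` with the per-day true total fly fluorescence.
#'
#' @param experiment result of [simulateVideoExperiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeExperiment <- function(experiment, dir) {
    cfg <- experiment$config
    rows <- list()
    for (d in seq_len(cfg@nDays)) for (v in seq_len(cfg@nVials))
        for (cam in seq_len(cfg@nCameras)) {
            st <- experiment$stacks[[d]][[v]][[cam]]
            sub <- sprintf("day%02d/cam%d", d - 1L, cam)
            dirP <- file.path(dir, sub)
            dir.create(dirP, recursive = TRUE, showWarnings = FALSE)
            for (f in seq_along(st@frames)) {
                fn <- sprintf("%s/vial%d_frame%04d.tif", sub, v, f - 1L)
                writeFrameTiff(st@frames[[f]], file.path(dir, fn))
                rows[[length(rows) + 1L]] <- data.frame(
                    filename = fn, frame_index = f - 1L,
                    camera_id = st@cameraId, vial_id = st@vialId,
                    day = st@day, fps = st@fps)
            }
        }
    utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    gt <- expand.grid(day = experiment$truth$days,
                      vial_id = colnames(experiment$truth$perDay),
                      stringsAsFactors = FALSE)
    gt$true_total_fluorescence <- experiment$truth$perDay[
        cbind(gt$day + 1L, match(gt$vial_id, colnames(experiment$truth$perDay)))]
    gt$true_slope <- experiment$truth$trueSlope
    gt$true_half_life <- cfg@trueHalfLife
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(dir)
}

#' Write / read a single frame as 16-bit grayscale TIFF
#'
#' @param frame numeric matrix with values in \[0, 65535\] (AU as 16-bit
#'   counts); written rounded to the nearest count.
#' @param path TIFF path.
#' @return `readFrameTiff` returns the frame as a numeric matrix in AU.
#' @export
writeFrameTiff <- function(frame, path) {
    if (max(frame) > tiffScale)
        stop("frame intensities exceed the 16-bit range (max ",
             round(max(frame)), " AU)")
    tiff::writeTIFF(round(frame) / tiffScale, path, bits.per.sample = 16L,
                    compression = "none")
    invisible(path)
}

#' @rdname writeFrameTiff
#' @export
readFrameTiff <- function(path) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * tiffScale)
}

#' Read the manifest of an experiment directory
#'
#' @param dir directory containing `manifest.csv`.
#' @return data.frame manifest.
#' @export
readManifest <- function(dir) {
    path <- file.path(dir, "manifest.csv")
    if (!file.exists(path)) stop("no manifest.csv in ", dir)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read one camera/vial/day frame stack from an experiment directory
#'
#' @param dir experiment directory (as written by [writeExperiment()]).
#' @param cameraId,vialId,day stack identity, matched against the manifest.
#' @param manifest optional pre-read manifest data.frame.
#' @return A [FrameStack-class].
#' @export
readFrameStack <- function(dir, cameraId, vialId, day, manifest = NULL) {
    if (is.null(manifest)) manifest <- readManifest(dir)
    sel <- manifest[manifest$camera_id == cameraId &
                    manifest$vial_id == vialId & manifest$day == day, ]
    if (!nrow(sel))
        stop("no frames for camera ", cameraId, ", vial ", vialId,
             ", day ", day, " in ", dir)
    sel <- sel[order(sel$frame_index), ]
    fr <- lapply(file.path(dir, sel$filename), readFrameTiff)
    frameStack(fr, fps = sel$fps[1], cameraId = cameraId, vialId = vialId,
               day = day)
}

#' Read an exclusion mask image
#'
#' @param path PNG or TIFF path; any nonzero pixel is excluded.
#' @return binary numeric matrix (0 = keep, 1 = exclude).
#' @export
readMask <- function(path) {
    if (!file.exists(path)) stop("mask file not found: ", path)
    img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
            stop("the png package is needed to read PNG masks")
        png::readPNG(path)
    } else tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    (img != 0) + 0
}
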