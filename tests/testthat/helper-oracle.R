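# Exhaustive per-pixel oracle for frame quantification: explicit loops and a
# BFS flood fill, sharing no code with the package's vectorised path.
oracleQuantify <- function(frame, threshold, roi, mask = NULL, minBlobPx = 1) {
    nr <- nrow(frame); nc <- ncol(frame)
    cand <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        inRoi <- (i - 1) >= roi[1] && (i - 1) < roi[2] &&
                 (j - 1) >= roi[3] && (j - 1) < roi[4]
        masked <- !is.null(mask) && mask[i, j] != 0
        cand[i, j] <- inRoi && !masked && frame[i, j] > threshold
    }
    visited <- matrix(FALSE, nr, nc)
    comps <- list()
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (cand[i, j] && !visited[i, j]) {
            queue <- list(c(i, j)); visited[i, j] <- TRUE
            px <- list()
            while (length(queue)) {
                p <- queue[[1]]; queue <- queue[-1]
                px[[length(px) + 1]] <- p
                for (di in -1:1) for (dj in -1:1) {
                    ni <- p[1] + di; nj <- p[2] + dj
                    if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
                        cand[ni, nj] && !visited[ni, nj]) {
                        visited[ni, nj] <- TRUE
                        queue[[length(queue) + 1]] <- c(ni, nj)
                    }
                }
            }
            comps[[length(comps) + 1]] <- px
        }
    }
    keep <- Filter(function(px) length(px) >= minBlobPx, comps)
    total <- 0
    for (px in keep) for (p in px) total <- total + frame[p[1], p[2]]
    list(total = total, n = length(keep))
}

# Random test frame with blobby structure plus speckle, and a random
# quantification setup (ROI, threshold, optional mask, blob-size floor).
randomQuantCase <- function(withMask = TRUE, maxSide = 32L) {
    nr <- sample(8:maxSide, 1); nc <- sample(8:maxSide, 1)
    frame <- matrix(stats::rpois(nr * nc, lambda = 3), nr, nc)
    for (b in seq_len(sample(0:4, 1))) {   # a few bright blocks
        r0 <- sample(nr, 1); c0 <- sample(nc, 1)
        rs <- r0:min(nr, r0 + sample(0:3, 1))
        cs <- c0:min(nc, c0 + sample(0:3, 1))
        frame[rs, cs] <- frame[rs, cs] + sample(20:100, 1)
    }
    r0 <- sample(0:(nr - 2), 1); c0 <- sample(0:(nc - 2), 1)
    roi <- c(r0, sample((r0 + 1):nr, 1), c0, sample((c0 + 1):nc, 1))
    mask <- NULL
    if (withMask && stats::runif(1) < 0.5)
        mask <- matrix(stats::rbinom(nr * nc, 1, 0.1), nr, nc)
    list(frame = frame, threshold = sample(0:30, 1), roi = roi, mask = mask,
         minBlobPx = sample(1:3, 1))
}

# Shorthand for building a FluorescenceSeries from per-frame totals.
makeSeries <- function(totals, nObj = NULL, cam = "cam1", vial = "vial1",
                       day = 0) {
    if (is.null(nObj)) nObj <- as.integer(totals > 0)
    new("FluorescenceSeries",
        records = data.frame(frame_index = seq_along(totals) - 1L,
                             total_fluorescence = as.numeric(totals),
                             n_objects = as.integer(nObj)),
        cameraId = cam, vialId = vial, day = as.numeric(day))
}

# Run the full video pipeline (quantify -> merge -> aggregate) on a simulated
# experiment and return the GroupTimecourse.
pipelineTimecourse <- function(ex, qc, signalThreshold = 0, group = "sim") {
    cfg <- ex$config
    rows <- list()
    for (d in seq_len(cfg@nDays)) for (v in seq_len(cfg@nVials)) {
        streams <- lapply(seq_len(cfg@nCameras), function(cam)
            quantifyStack(ex$stacks[[d]][[v]][[cam]], qc))
        merged <- if (length(streams) == 1L) streams[[1]]
                  else Reduce(function(a, b)
                      mergeCameras(a, b, signalThreshold), streams)
        rows[[length(rows) + 1L]] <- data.frame(
            vial_id = paste0("vial", v), day = d - 1L,
            value = vialDayValue(merged))
    }
    aggregateGroup(do.call(rbind, rows), group)
}
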