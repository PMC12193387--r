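#' Build a quantification configuration
#'
#' @param threshold pixel detection threshold (AU); a pixel is a candidate
#'   only if its raw intensity is strictly greater than `threshold`.
#' @param roi region of interest as `c(rowMin, rowMax, colMin, colMax)`,
#'   0-based, half-open (so `c(0, nrow, 0, ncol)` is the full frame).
#' @param mask optional exclusion mask: a matrix of the same shape as the
#'   frames whose nonzero pixels are excluded (e.g. background
#'   autofluorescence spots).
#' @param minBlobPx minimum 8-connected component size (pixels) for a
#'   component to count as a fly. Default 1 keeps pure threshold semantics.
#' @return A [QuantConfig-class].
#' @examples
#' quantConfig(threshold = 10, roi = c(0, 64, 0, 64))
#' @export
quantConfig <- function(threshold, roi, mask = NULL, minBlobPx = 1L) {
    if (!is.null(mask)) mask <- as.matrix(mask)
    new("QuantConfig", threshold = as.numeric(threshold),
        roi = as.integer(roi), mask = mask, minBlobPx = as.integer(minBlobPx))
}

#' Construct a frame stack
#'
#' @param frames list of same-shaped non-negative numeric matrices.
#' @param fps frames per second.
#' @param cameraId,vialId labels.
#' @param day time point (days).
#' @return A [FrameStack-class].
#' @export
frameStack <- function(frames, fps = 30, cameraId = "cam1", vialId = "vial1",
                       day = 0) {
    new("FrameStack", frames = frames, fps = as.numeric(fps),
        cameraId = as.character(cameraId), vialId = as.character(vialId),
        day = as.numeric(day))
}

# 8-connected component labelling. Candidate pixels become graph vertices,
# 8-neighbour adjacencies become edges (built vectorised from 4 directional
# shifts; the other 4 are their reverses), and connected components are read
# off the graph. Returns an integer matrix: 0 background, 1..k component ids.
labelComponents <- function(cand) {
    nr <- nrow(cand); nc <- ncol(cand)
    idx <- which(cand)
    n <- length(idx)
    out <- matrix(0L, nr, nc)
    if (!n) return(out)
    vid <- integer(nr * nc)
    vid[idx] <- seq_len(n)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    edges <- list()
    for (s in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))) {
        r2 <- rows + s[1]; c2 <- cols + s[2]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        nb <- (c2[ok] - 1L) * nr + r2[ok]
        hit <- cand[nb]
        edges[[length(edges) + 1L]] <-
            rbind(vid[idx[ok][hit]], vid[nb[hit]])
    }
    edges <- do.call(cbind, edges)
    memb <- if (length(edges)) {
        g <- igraph::make_graph(as.vector(edges), n = n, directed = FALSE)
        igraph::components(g)$membership
    } else seq_len(n)
    out[idx] <- as.integer(memb)
    out
}

#' Quantify total fly fluorescence in one frame
#'
#' The per-frame detection rule: candidate pixels are those inside the ROI,
#' not excluded by the mask, with raw intensity strictly greater than the
#' threshold. Candidates are grouped into 8-connected components; components
#' of at least `minBlobPx` pixels are counted as flies, and the total
#' fluorescence is the sum of raw intensities over their pixels (no
#' background subtraction — background is minimized experimentally, not
#' computationally).
#'
#' @param frame 2-D non-negative numeric matrix (AU).
#' @param config a [QuantConfig-class].
#' @return One-row data.frame with `total_fluorescence` and `n_objects`.
#' @examples
#' f <- matrix(1, 5, 5); f[2:3, 2:3] <- 100
#' quantifyFrame(f, quantConfig(10, c(0, 5, 0, 5)))  # total 400, 1 object
#' @export
quantifyFrame <- function(frame, config) {
    stopifnot(is(config, "QuantConfig"))
    frame <- as.matrix(frame)
    r <- config@roi
    if (r[2] > nrow(frame) || r[4] > ncol(frame))
        stop("roi (", paste(r, collapse = ", "),
             ") does not fit inside the frame (", nrow(frame), "x",
             ncol(frame), ")")
    if (!is.null(config@mask) && !all(dim(config@mask) == dim(frame)))
        stop("mask shape (", paste(dim(config@mask), collapse = "x"),
             ") does not match frame shape (",
             paste(dim(frame), collapse = "x"), ")")
    rows <- (r[1] + 1L):r[2]
    cols <- (r[3] + 1L):r[4]
    sub <- frame[rows, cols, drop = FALSE]
    cand <- sub > config@threshold
    if (!is.null(config@mask))
        cand <- cand & (config@mask[rows, cols, drop = FALSE] == 0)
    if (!any(cand))
        return(data.frame(total_fluorescence = 0, n_objects = 0L))
    lab <- labelComponents(cand)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= config@minBlobPx)
    if (!length(keep))
        return(data.frame(total_fluorescence = 0, n_objects = 0L))
    sel <- lab %in% keep
    data.frame(total_fluorescence = as.numeric(sum(sub[sel])),
               n_objects = length(keep))
}

#' @describeIn quantifyStack Quantify each frame of a [FrameStack-class].
setMethod("quantifyStack", signature("FrameStack", "QuantConfig"),
    function(stack, config) {
        if (!length(stack@frames)) stop("empty frame stack")
        recs <- vector("list", length(stack@frames))
        for (i in seq_along(stack@frames)) {
            recs[[i]] <- tryCatch(quantifyFrame(stack@frames[[i]], config),
                error = function(e) stop("frame ", i, ": ",
                                         conditionMessage(e), call. = FALSE))
        }
        recs <- do.call(rbind, recs)
        recs <- data.frame(frame_index = seq_len(nrow(recs)) - 1L, recs)
        new("FluorescenceSeries", records = recs, cameraId = stack@cameraId,
            vialId = stack@vialId, day = stack@day)
    })

#' Extract one channel from a colour frame
#'
#' Video quantification operates on single-channel intensity frames; colour
#' input (e.g. RGB captures) must first be reduced to the reporter's emission
#' channel — green for eGFP-class reporters, red for DsRED/mCherry-class.
#'
#' @param frame 3-D array (rows x cols x channels) or a matrix (returned
#'   unchanged).
#' @param channel `"green"`, `"red"`, `"blue"`, or a channel index.
#' @return 2-D numeric matrix.
#' @export
extractChannel <- function(frame, channel = "green") {
    if (is.matrix(frame)) return(frame)
    if (length(dim(frame)) != 3L)
        stop("frame must be a matrix or a rows x cols x channels array")
    idx <- if (is.numeric(channel)) as.integer(channel)
           else match(match.arg(channel, c("red", "green", "blue")),
                      c("red", "green", "blue"))
    if (idx < 1L || idx > dim(frame)[3]) stop("channel index out of range")
    frame[, , idx]
}
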