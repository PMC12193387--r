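#' Build a simulation configuration
#'
#' Defaults mirror the in vivo assay design: 6 flies per vial, 4 replicate
#' vials, 2 synchronized cameras, 30 fps recordings taken daily over 6 days,
#' fluorescence peaking one day after induction ends and decaying with a
#' half-life of 3.5 days. Frame geometry, background level and noise are not
#' fixed by the assay and are free parameters (see the methods vignette).
#'
#' @param nFlies flies per vial.
#' @param flyRadiusPx fly disk radius (px).
#' @param flyPeakIntensity per-pixel fly intensity at the peak day (AU).
#' @param backgroundLevel background intensity (AU).
#' @param noiseSd additive per-pixel Gaussian noise SD (AU).
#' @param frameShape frame (height, width) in pixels.
#' @param roi vial region (rowMin, rowMax, colMin, colMax), 0-based
#'   half-open; default leaves a 2-px border.
#' @param nFramesPerDay frames per daily recording per camera.
#' @param fps frame rate.
#' @param nDays daily time points.
#' @param trueHalfLife programmed half-life (days).
#' @param peakDay day index (0-based) of peak intensity.
#' @param nVials replicate vials.
#' @param nCameras cameras per vial.
#' @param stepSd random-walk step SD (px/frame).
#' @param seed integer RNG seed.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nFlies = 6L, flyRadiusPx = 3L, flyPeakIntensity = 10000,
                      backgroundLevel = 50, noiseSd = 200,
                      frameShape = c(64L, 64L), roi = NULL,
                      nFramesPerDay = 30L, fps = 30, nDays = 6L,
                      trueHalfLife = 3.5, peakDay = 1L, nVials = 4L,
                      nCameras = 2L, stepSd = 2, seed = 1L) {
    frameShape <- as.integer(frameShape)
    if (is.null(roi))
        roi <- c(2L, frameShape[1] - 2L, 2L, frameShape[2] - 2L)
    new("SimConfig", nFlies = as.integer(nFlies),
        flyRadiusPx = as.integer(flyRadiusPx),
        flyPeakIntensity = as.numeric(flyPeakIntensity),
        backgroundLevel = as.numeric(backgroundLevel),
        noiseSd = as.numeric(noiseSd), frameShape = frameShape,
        roi = as.integer(roi), nFramesPerDay = as.integer(nFramesPerDay),
        fps = as.numeric(fps), nDays = as.integer(nDays),
        trueHalfLife = as.numeric(trueHalfLife), peakDay = as.integer(peakDay),
        nVials = as.integer(nVials), nCameras = as.integer(nCameras),
        stepSd = as.numeric(stepSd), seed = as.integer(seed))
}

# Disk pixel offsets for a fly of radius r: all (dr, dc) with dr^2+dc^2 <= r^2.
diskOffsets <- function(r) {
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Per-day per-pixel fly intensity: exponential decay after the peak, linear
# induction ramp before it (the ramp shape is unconstrained by the decay fit).
dayIntensity <- function(config) {
    d <- 0:(config@nDays - 1L)
    ifelse(d >= config@peakDay,
           config@flyPeakIntensity *
               2^(-(d - config@peakDay) / config@trueHalfLife),
           config@flyPeakIntensity * (d + 1) / (config@peakDay + 1))
}

# Reflect a coordinate into [lo, hi].
reflect <- function(x, lo, hi) {
    if (hi <= lo) return(rep(lo, length(x)))
    w <- hi - lo
    x <- abs(x - lo) %% (2 * w)
    lo + ifelse(x > w, 2 * w - x, x)
}

# Sample non-overlapping fly centres and walk them for nFrames steps.
# Returns an nFrames x nFlies x 2 array of rounded pixel centres.
walkFlies <- function(config, nFrames) {
    r <- config@flyRadiusPx
    roi <- config@roi
    loR <- roi[1] + 1L + r; hiR <- roi[2] - r
    loC <- roi[3] + 1L + r; hiC <- roi[4] - r
    if (hiR < loR || hiC < loC)
        stop("frame too small: the ROI cannot contain a fly of radius ", r)
    area <- (hiR - loR + 1) * (hiC - loC + 1)
    if (config@nFlies * (2 * r + 1)^2 > area)
        stop("frame too small to place ", config@nFlies,
             " non-overlapping flies of radius ", r, " inside the ROI")
    sep2 <- (2 * r + 1)^2   # squared centre distance for non-overlap
    pos <- matrix(NA_real_, config@nFlies, 2)
    for (i in seq_len(config@nFlies)) {
        ok <- FALSE
        for (try in 1:2000) {
            p <- c(stats::runif(1, loR, hiR), stats::runif(1, loC, hiC))
            if (i == 1L || all((pos[seq_len(i - 1L), 1] - p[1])^2 +
                               (pos[seq_len(i - 1L), 2] - p[2])^2 >= sep2)) {
                pos[i, ] <- p; ok <- TRUE; break
            }
        }
        if (!ok)
            stop("frame too small to place ", config@nFlies,
                 " non-overlapping flies of radius ", r, " inside the ROI")
    }
    out <- array(NA_integer_, c(nFrames, config@nFlies, 2))
    for (f in seq_len(nFrames)) {
        if (f > 1L) {
            for (i in seq_len(config@nFlies)) {
                for (try in 1:20) {
                    cand <- pos[i, ] + stats::rnorm(2, sd = config@stepSd)
                    cand[1] <- reflect(cand[1], loR, hiR)
                    cand[2] <- reflect(cand[2], loC, hiC)
                    others <- setdiff(seq_len(config@nFlies), i)
                    if (!length(others) ||
                        all((pos[others, 1] - cand[1])^2 +
                            (pos[others, 2] - cand[2])^2 >= sep2)) {
                        pos[i, ] <- cand; break
                    }
                }
            }
        }
        out[f, , ] <- round(pos)
    }
    out
}

# Render one frame: background everywhere, fly disks set to `intensity`,
# then additive Gaussian noise clipped at zero.
renderFrame <- function(config, centres, intensity, disk) {
    h <- config@frameShape[1]; w <- config@frameShape[2]
    frame <- matrix(config@backgroundLevel, h, w)
    for (i in seq_len(nrow(centres))) {
        rr <- centres[i, 1] + disk$dr
        cc <- centres[i, 2] + disk$dc
        frame[cbind(rr, cc)] <- intensity
    }
    if (config@noiseSd > 0)
        frame <- pmax(frame + matrix(stats::rnorm(h * w, sd = config@noiseSd),
                                     h, w), 0)
    frame
}

#' Simulate a dual-camera video turnover experiment
#'
#' Generates, for every day, vial and camera, a [FrameStack-class] of frames
#' showing `nFlies` uniform-intensity disks performing a reflected Gaussian
#' random walk inside the vial ROI on a dim background, with per-pixel
#' additive Gaussian noise clipped at zero. Fly intensity rises linearly to
#' the peak day and then decays exponentially with the programmed half-life,
#' so the noiseless per-frame fly fluorescence is known exactly. The two
#' cameras are independent position realizations of the same vial (the
#' pipeline sums intensities; it never triangulates). Flies are kept
#' non-overlapping so the rendered blob total is exactly
#' `nFlies * diskArea * intensity(day)`.
#'
#' @param config a [SimConfig-class].
#' @param returnTrajectories keep per-frame fly centres in the output
#'   (memory-heavy; off by default).
#' @return A list with elements:
#'   \describe{
#'     \item{stacks}{nested list `stacks[[day]][[vial]][[camera]]` of
#'       [FrameStack-class] objects (days indexed 1..nDays for day 0..nDays-1).}
#'     \item{truth}{ground truth: `perDay` (days x vials matrix of true total
#'       fly fluorescence per frame, AU), `dayIntensity`, `diskArea`,
#'       `trueSlope` (= -ln 2 / trueHalfLife, per day), `days`, and optionally
#'       `trajectories`.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' ex <- simulateVideoExperiment(simConfig(nVials = 1L, nDays = 3L,
#'                                         nFramesPerDay = 2L, seed = 7L))
#' ex$truth$perDay
#' @export
simulateVideoExperiment <- function(config, returnTrajectories = FALSE) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    disk <- diskOffsets(config@flyRadiusPx)
    intensity <- dayIntensity(config)
    diskArea <- nrow(disk)
    perDay <- outer(intensity * config@nFlies * diskArea,
                    rep(1, config@nVials))
    dimnames(perDay) <- list(day = 0:(config@nDays - 1L),
                             vial = paste0("vial", seq_len(config@nVials)))
    stacks <- vector("list", config@nDays)
    traj <- if (returnTrajectories) list() else NULL
    for (d in seq_len(config@nDays)) {
        stacks[[d]] <- vector("list", config@nVials)
        for (v in seq_len(config@nVials)) {
            stacks[[d]][[v]] <- vector("list", config@nCameras)
            for (cam in seq_len(config@nCameras)) {
                centres <- walkFlies(config, config@nFramesPerDay)
                fr <- lapply(seq_len(config@nFramesPerDay), function(f)
                    renderFrame(config, matrix(centres[f, , ], ncol = 2),
                                intensity[d], disk))
                stacks[[d]][[v]][[cam]] <- frameStack(
                    fr, fps = config@fps, cameraId = paste0("cam", cam),
                    vialId = paste0("vial", v), day = d - 1L)
                if (returnTrajectories)
                    traj[[sprintf("day%d_vial%d_cam%d", d - 1L, v, cam)]] <-
                        centres
            }
        }
    }
    truth <- list(perDay = perDay, dayIntensity = intensity,
                  diskArea = diskArea,
                  trueSlope = -log(2) / config@trueHalfLife,
                  days = 0:(config@nDays - 1L))
    if (returnTrajectories) truth$trajectories <- traj
    list(stacks = stacks, truth = truth, config = config)
}

#' Simulate a plate-reader fluorescence decay series
#'
#' First-order decay sampled at fixed intervals (30 s in the in vitro
#' proteasome assay), with multiplicative lognormal noise of a given
#' coefficient of variation. Times are reported in minutes.
#'
#' @param trueHalfLifeMin true half-life in minutes.
#' @param durationMin total duration in minutes.
#' @param intervalS sampling interval in seconds (default 30).
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (0 for a noiseless series).
#' @param f0 fluorescence at time zero (AU).
#' @param seed integer RNG seed.
#' @return data.frame with `time_min` and `fluorescence`.
#' @examples
#' s <- simulatePlateSeries(78, 156, noiseCv = 0)
#' s$fluorescence[s$time_min == 78] / s$fluorescence[1]  # 0.5
#' @export
simulatePlateSeries <- function(trueHalfLifeMin, durationMin, intervalS = 30,
                                noiseCv = 0, f0 = 1000, seed = 1L) {
    if (trueHalfLifeMin <= 0) stop("trueHalfLifeMin must be > 0")
    set.seed(as.integer(seed))
    t <- seq(0, durationMin, by = intervalS / 60)
    f <- f0 * 2^(-t / trueHalfLifeMin)
    if (noiseCv > 0) {
        sdlog <- sqrt(log(1 + noiseCv^2))
        f <- f * stats::rlnorm(length(t), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    data.frame(time_min = t, fluorescence = f)
}

#' Simulate a half-life table stratified by age and sex
#'
#' Draws half-life values from a balanced two-factor linear model
#' (age group x sex, with interaction) plus Gaussian residual noise — the
#' design used to test age and sex effects on reporter half-life.
#'
#' @param nPerCell replicates per (age, sex) cell (>= 2).
#' @param effects list with elements `age`, `sex`, `interaction` (days):
#'   `age` is added for old flies, `sex` for females, `interaction` for old
#'   females.
#' @param residualSd residual SD (days).
#' @param baseline half-life of young males (days).
#' @param seed integer RNG seed.
#' @return data.frame with `half_life`, `age_group` (young/old), `sex`
#'   (male/female), `experiment_id`.
#' @export
simulateHalflifeTable <- function(nPerCell,
                                  effects = list(age = 0, sex = 0,
                                                 interaction = 0),
                                  residualSd = 0.5, baseline = 3.9,
                                  seed = 1L) {
    if (nPerCell < 2L) stop("nPerCell must be >= 2")
    set.seed(as.integer(seed))
    grid <- expand.grid(age_group = c("young", "old"),
                        sex = c("male", "female"),
                        rep = seq_len(nPerCell), stringsAsFactors = FALSE)
    mu <- baseline +
        effects$age * (grid$age_group == "old") +
        effects$sex * (grid$sex == "female") +
        effects$interaction * (grid$age_group == "old" & grid$sex == "female")
    data.frame(half_life = mu + stats::rnorm(nrow(grid), sd = residualSd),
               age_group = grid$age_group, sex = grid$sex,
               experiment_id = sprintf("exp%02d", grid$rep),
               stringsAsFactors = FALSE)
}

#' Simulate a group fluorescence time course directly
#'
#' A lightweight generator for statistical validation: per-vial daily mean
#' fluorescence following exponential decay from a peak, with multiplicative
#' lognormal noise of a given coefficient of variation, assembled into a
#' [GroupTimecourse-class]. Skips the video layer entirely.
#'
#' @param days time points (days), strictly increasing.
#' @param peakValue fluorescence at `peakDay` (AU).
#' @param trueHalfLife half-life in days.
#' @param peakDay day of the peak (default: first day, i.e. decay-only).
#' @param noiseCv per-vial per-day coefficient of variation.
#' @param nVials replicate vials.
#' @param group group label.
#' @param seed integer RNG seed.
#' @return A [GroupTimecourse-class].
#' @export
simulateTimecourse <- function(days, peakValue, trueHalfLife,
                               peakDay = days[1], noiseCv = 0, nVials = 4L,
                               group = "group", seed = 1L) {
    if (trueHalfLife <= 0) stop("trueHalfLife must be > 0")
    set.seed(as.integer(seed))
    mu <- ifelse(days >= peakDay,
                 peakValue * 2^(-(days - peakDay) / trueHalfLife),
                 peakValue * 2^((days - peakDay) / trueHalfLife))
    vm <- matrix(rep(mu, each = nVials), nrow = nVials)
    if (noiseCv > 0) {
        sdlog <- sqrt(log(1 + noiseCv^2))
        vm <- vm * matrix(stats::rlnorm(length(vm), meanlog = -sdlog^2 / 2,
                                        sdlog = sdlog), nrow = nVials)
    }
    rownames(vm) <- paste0("vial", seq_len(nVials))
    groupTimecourseFromMatrix(vm, days, group)
}
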