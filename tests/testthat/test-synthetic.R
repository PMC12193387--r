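test_that("identical seed and config give bit-identical output at every stage", {
    cfg <- simConfig(nVials = 1L, nDays = 3L, nFramesPerDay = 3L,
                     noiseSd = 150, seed = 11L)
    ex1 <- simulateVideoExperiment(cfg)
    ex2 <- simulateVideoExperiment(cfg)
    expect_identical(ex1$stacks, ex2$stacks)
    expect_identical(ex1$truth, ex2$truth)
    expect_identical(simulatePlateSeries(78, 60, noiseCv = 0.1, seed = 5L),
                     simulatePlateSeries(78, 60, noiseCv = 0.1, seed = 5L))
    expect_identical(simulateHalflifeTable(3L, residualSd = 1, seed = 9L),
                     simulateHalflifeTable(3L, residualSd = 1, seed = 9L))
})

test_that("noiseless single-fly intensity halves per day at half-life 1", {
    cfg <- simConfig(nFlies = 1L, nVials = 1L, nDays = 2L, nFramesPerDay = 1L,
                     noiseSd = 0, trueHalfLife = 1, peakDay = 0L, seed = 2L)
    ex <- simulateVideoExperiment(cfg)
    qc <- quantConfig(cfg@backgroundLevel, cfg@roi)
    t0 <- quantifyFrame(ex$stacks[[1]][[1]][[1]]@frames[[1]], qc)
    t1 <- quantifyFrame(ex$stacks[[2]][[1]][[1]]@frames[[1]], qc)
    expect_equal(t1$total_fluorescence, t0$total_fluorescence / 2)
    expect_equal(ex$truth$perDay[2, 1], ex$truth$perDay[1, 1] / 2)
})

test_that("noiseless quantification matches the recorded ground truth exactly", {
    cfg <- simConfig(nVials = 2L, nDays = 3L, nFramesPerDay = 2L,
                     noiseSd = 0, seed = 4L)
    ex <- simulateVideoExperiment(cfg)
    qc <- quantConfig(cfg@backgroundLevel, cfg@roi)
    for (d in 1:3) for (v in 1:2) for (cam in 1:2) {
        s <- quantifyStack(ex$stacks[[d]][[v]][[cam]], qc)
        expect_equal(totalFluorescence(s),
                     rep(ex$truth$perDay[d, v], 2))
    }
    # and against an independent brute-force pixel sum over one frame
    fr <- ex$stacks[[2]][[1]][[1]]@frames[[1]]
    brute <- 0
    for (i in seq_len(nrow(fr))) for (j in seq_len(ncol(fr)))
        if (fr[i, j] > cfg@backgroundLevel) brute <- brute + fr[i, j]
    expect_equal(brute, ex$truth$perDay[2, 1])
})

test_that("noiseless ground truth decays exactly exponentially after the peak", {
    cfg <- simConfig(nVials = 1L, nDays = 6L, nFramesPerDay = 1L, noiseSd = 0,
                     trueHalfLife = 2.4, peakDay = 1L, seed = 6L)
    ex <- simulateVideoExperiment(cfg)
    post <- 2:6   # day indices 1..5 (peak at day 1)
    lnF <- log(ex$truth$perDay[post, 1])
    slopes <- diff(lnF) / diff(ex$truth$days[post])
    expect_equal(unname(slopes), rep(-log(2) / 2.4, 4), tolerance = 1e-12)
    expect_equal(ex$truth$trueSlope, -log(2) / 2.4)
})

test_that("an overcrowded frame is rejected with the non-overlap constraint named", {
    cfg <- simConfig(nFlies = 30L, frameShape = c(12L, 12L),
                     flyRadiusPx = 2L, nVials = 1L, nDays = 1L,
                     nFramesPerDay = 1L, peakDay = 0L, seed = 1L)
    expect_error(simulateVideoExperiment(cfg), "non-overlapping")
})

test_that("plate-reader series follows the programmed decay", {
    s <- simulatePlateSeries(78, 156, noiseCv = 0, f0 = 1200)
    expect_equal(s$time_min, seq(0, 156, by = 0.5))
    expect_equal(s$fluorescence[s$time_min == 78], 600)
    expect_equal(s$fluorescence[s$time_min == 156], 300)
    fit <- fitDecay(s$time_min, s$fluorescence, timeUnit = "minutes")
    expect_equal(decaySlope(fit), -log(2) / 78, tolerance = 1e-12)
    expect_equal(halfLife(fit), 78, tolerance = 1e-12)
})

test_that("half-life tables are balanced and carry the programmed effects", {
    tab <- simulateHalflifeTable(5L, residualSd = 0.3, seed = 7L)
    expect_true(all(table(tab$age_group, tab$sex) == 5L))
    expect_true(all(tab$half_life > 0))
    # a strong pure age effect is detected in one draw
    tab2 <- simulateHalflifeTable(10L, effects = list(age = 2.5, sex = 0,
                                                      interaction = 0),
                                  residualSd = 0.5, seed = 8L)
    an <- halflifeAnova(tab2)
    expect_lt(an["age_group", "Pr(>F)"], 0.01)
    # effect-free noiseless table: documented F = 0, p = 1 convention
    tab3 <- simulateHalflifeTable(3L, residualSd = 0, seed = 1L)
    an3 <- halflifeAnova(tab3)
    expect_true(attr(an3, "degenerate"))
    expect_equal(unname(an3[c("age_group", "sex", "age_group:sex"),
                            "F value"]), c(0, 0, 0))
})

test_that("simulateTimecourse reproduces the closed-form decay when noiseless", {
    tc <- simulateTimecourse(0:5, peakValue = 1000, trueHalfLife = 2,
                             noiseCv = 0, nVials = 3L, seed = 1L)
    expect_s4_class(tc, "GroupTimecourse")
    expect_equal(groupMean(tc), 1000 * 2^(-(0:5) / 2))
    expect_equal(groupSd(tc), rep(0, 6))
})
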