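test_that("camera merging sums per-frame totals and filters sub-threshold frames", {
    a <- makeSeries(c(10, 0, 5), cam = "cam1")
    b <- makeSeries(c(10, 0, 5), cam = "cam2")
    m <- suppressMessages(mergeCameras(a, b, signalThreshold = 4))
    expect_equal(totalFluorescence(m), c(20, 10))
    expect_equal(m@records$frame_index, c(0L, 2L))
    expect_equal(cameraId(m), c("cam1", "cam2"))
    # threshold 0 with strictly positive totals keeps every frame
    a2 <- makeSeries(c(3, 1, 2)); b2 <- makeSeries(c(1, 1, 1), cam = "cam2")
    expect_equal(nrow(mergeCameras(a2, b2, 0)@records), 3L)
    # commutative
    m1 <- suppressMessages(mergeCameras(a, b, 4))
    m2 <- suppressMessages(mergeCameras(b, a, 4))
    expect_equal(totalFluorescence(m1), totalFluorescence(m2))
})

test_that("unsynchronized streams are rejected", {
    a <- makeSeries(c(1, 2, 3))
    expect_error(mergeCameras(a, makeSeries(c(1, 2)), 0), "synchronized")
    bad <- makeSeries(c(1, 2, 3)); bad@records$frame_index <- c(0L, 2L, 3L)
    expect_error(mergeCameras(a, bad, 0), "synchronized")
    expect_error(mergeCameras(a, makeSeries(c(1, 2, 3), vial = "other"), 0),
                 "identity")
})

test_that("a vial's daily value is the mean of surviving frame totals", {
    expect_equal(vialDayValue(makeSeries(c(20, 10))), 15)
    expect_equal(vialDayValue(makeSeries(rep(7, 5))), 7)
    empty <- suppressMessages(mergeCameras(makeSeries(c(1, 1)),
                                           makeSeries(c(1, 1), cam = "cam2"),
                                           signalThreshold = 10))
    expect_warning(v <- vialDayValue(empty), "no signal")
    expect_true(is.na(v))
})

test_that("group aggregation computes cross-vial mean and sample SD", {
    df <- expand.grid(vial_id = paste0("v", 1:4), day = 0:2,
                      stringsAsFactors = FALSE)
    df$value <- 100 - 10 * df$day          # all vials identical
    tc <- aggregateGroup(df, "g")
    expect_equal(groupMean(tc), c(100, 90, 80))
    expect_equal(groupSd(tc), c(0, 0, 0))
})

test_that("aggregation handles two-vial SD, single vials, and missing days", {
    df2 <- data.frame(vial_id = c("a", "b"), day = 0, value = c(2, 4))
    tc2 <- aggregateGroup(df2, "g")
    expect_equal(groupMean(tc2), 3)
    expect_equal(groupSd(tc2), sqrt(2))
    # single vial: mean is that vial, SD missing
    tc1 <- aggregateGroup(data.frame(vial_id = "a", day = 0:1,
                                     value = c(5, 4)), "g")
    expect_equal(groupMean(tc1), c(5, 4))
    expect_true(all(is.na(groupSd(tc1))))
    # missing vial-day flagged, mean over available vials
    df3 <- data.frame(vial_id = c("a", "a", "b"), day = c(0, 1, 0),
                      value = c(2, 1, 4))
    expect_warning(tc3 <- aggregateGroup(df3, "g"), "missing")
    expect_equal(groupMean(tc3), c(3, 1))
    expect_equal(groupSd(tc3), c(sqrt(2), NA))
    expect_error(aggregateGroup(data.frame(vial_id = character(),
                                           day = numeric(),
                                           value = numeric()), "g"),
                 "no vials")
})

test_that("aggregation is invariant to vial order", {
    df <- expand.grid(vial_id = paste0("v", 1:4), day = 0:3,
                      stringsAsFactors = FALSE)
    set.seed(3); df$value <- stats::runif(nrow(df), 50, 150)
    tc <- aggregateGroup(df, "g")
    tcR <- aggregateGroup(df[rev(seq_len(nrow(df))), ], "g")
    expect_equal(groupMean(tc), groupMean(tcR))
    expect_equal(groupSd(tc), groupSd(tcR))
})

test_that("merging then averaging equals summing per-camera averages when nothing is filtered", {
    set.seed(8)
    a <- makeSeries(stats::runif(20, 1, 100))
    b <- makeSeries(stats::runif(20, 1, 100), cam = "cam2")
    merged <- mergeCameras(a, b, 0)
    expect_equal(vialDayValue(merged),
                 mean(totalFluorescence(a)) + mean(totalFluorescence(b)))
})

test_that("summary and per-frame CSVs round-trip exactly", {
    set.seed(5)
    vm <- matrix(stats::runif(12, 10, 1000) / 3, 3,
                 dimnames = list(paste0("vial", 1:3), NULL))
    tc <- aggregateGroup(vm, "control", days = c(0, 1, 2.5, 4))
    path <- tempfile(fileext = ".csv")
    writeSummaryCsv(tc, path)
    back <- readSummaryCsv(path)
    expect_identical(groupMean(back), groupMean(tc))
    expect_identical(groupSd(back), groupSd(tc))
    expect_identical(days(back), days(tc))
    expect_identical(unname(vialMeans(back)), unname(vialMeans(tc)))
    expect_identical(groupLabel(back), "control")

    s <- makeSeries(c(10.25, stats::runif(3)), day = 3)
    p2 <- tempfile(fileext = ".csv")
    writeSeriesCsv(s, p2)
    s2 <- readSeriesCsv(p2)
    expect_identical(totalFluorescence(s2), totalFluorescence(s))
    expect_identical(s2@records$frame_index, s@records$frame_index)
    expect_identical(assayDay(s2), 3)
})
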