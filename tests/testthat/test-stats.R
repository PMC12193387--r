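lnPts <- function(times, slope, intercept = 5, noise = 0) {
    data.frame(time = times,
               ln_fluorescence = intercept + slope * times +
                   stats::rnorm(length(times), sd = noise))
}

test_that("identical groups give interaction F = 0, p = 1 (degenerate flagged)", {
    g <- lnPts(0:4, -0.3)
    res <- compareSlopesAncova(list(a = g, b = g))
    expect_equal(res$interactionF, 0)
    expect_equal(res$pValue, 1)
    expect_true(res$degenerate)
})

test_that("perfectly separated noiseless slopes give p ~ 0 with the degeneracy flag", {
    res <- compareSlopesAncova(list(a = lnPts(0:4, -0.2),
                                    b = lnPts(0:4, -0.4)))
    expect_equal(res$pValue, 0)
    expect_true(res$degenerate)
    expect_equal(unname(res$slopes), c(-0.2, -0.4), tolerance = 1e-12)
})

test_that("ANCOVA matches a directly-computed pooled interaction F-test", {
    set.seed(42)
    a <- lnPts(0:5, -0.25, noise = 0.08)
    b <- lnPts(0:5, -0.10, noise = 0.08)
    res <- compareSlopesAncova(list(ctrl = a, drug = b))
    pooled <- rbind(cbind(a, g = "ctrl"), cbind(b, g = "drug"))
    full <- stats::lm(ln_fluorescence ~ time * g, pooled)
    reduced <- stats::lm(ln_fluorescence ~ time + g, pooled)
    cmp <- stats::anova(reduced, full)
    expect_equal(res$interactionF, cmp$F[2], tolerance = 1e-10)
    expect_equal(res$pValue, cmp$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(res$df, c(1, 8))
    expect_false(res$degenerate)
})

test_that("ANCOVA input validation names the offending group", {
    expect_error(compareSlopesAncova(list(a = lnPts(0:4, -1))), "2 groups")
    expect_error(compareSlopesAncova(list(a = lnPts(0:4, -1),
                                          short = lnPts(0:1, -1))),
                 "short")
})

test_that("half-life t-tests behave like unpaired two-tailed tests", {
    a <- c(1, 2, 3); b <- c(11, 12, 13)
    ht <- compareHalflivesTtest(a, b)
    expect_lt(ht$p.value, 0.01)
    ht2 <- compareHalflivesTtest(b, a)
    expect_equal(unname(ht2$statistic), -unname(ht$statistic))
    expect_equal(ht2$p.value, ht$p.value)
    same <- compareHalflivesTtest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(unname(same$statistic), 0)
    expect_equal(same$p.value, 1)
    expect_error(compareHalflivesTtest(1, c(1, 2)), "at least 2")
})

test_that("pooled t-test p-values track an exact permutation test on small samples", {
    set.seed(101)
    for (i in 1:8) {
        a <- stats::rnorm(5, mean = i %% 3); b <- stats::rnorm(6)
        pT <- compareHalflivesTtest(a, b, pooled = TRUE)$p.value
        # exact permutation distribution of the mean difference
        pool <- c(a, b); n <- length(a)
        splits <- utils::combn(length(pool), n)
        obs <- abs(mean(a) - mean(b))
        perm <- apply(splits, 2, function(ix)
            abs(mean(pool[ix]) - mean(pool[-ix])))
        pPerm <- mean(perm >= obs - 1e-12)
        expect_lt(abs(pT - pPerm), 0.1)
    }
})

test_that("two-factor ANOVA is sequential and matches Type-II on balanced designs", {
    tab <- simulateHalflifeTable(8L, effects = list(age = 1, sex = 0.5,
                                                    interaction = 0.3),
                                 residualSd = 0.6, seed = 13L)
    an <- halflifeAnova(tab)
    expect_equal(rownames(an),
                 c("age_group", "sex", "age_group:sex", "Residuals"))
    fit <- stats::lm(half_life ~ age_group * sex, tab)
    t2 <- car::Anova(fit, type = 2)
    for (term in c("age_group", "sex", "age_group:sex"))
        expect_equal(an[term, "Sum Sq"], t2[term, "Sum Sq"],
                     tolerance = 1e-10)
})

test_that("ANOVA rejects unidentifiable tables and sparse factors", {
    tab <- simulateHalflifeTable(3L, seed = 2L)
    expect_error(halflifeAnova(tab[tab$sex == "male", ]), "2 levels")
    expect_error(halflifeAnova(tab[!(tab$age_group == "old" &
                                     tab$sex == "female"), ]), "empty")
    expect_error(halflifeAnova(data.frame(half_life = 1:4)), "columns")
})

test_that("null ANOVA p-values are uniform across seeds", {
    ps <- vapply(1:200, function(s) {
        tab <- simulateHalflifeTable(4L, residualSd = 0.5, seed = s)
        halflifeAnova(tab)["age_group", "Pr(>F)"]
    }, numeric(1))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("peak comparisons separate 3x-different groups and demand replication", {
    set.seed(21)
    ctrl <- stats::rnorm(4, 100, 5); btz <- stats::rnorm(4, 300, 15)
    ht <- comparePeaks(ctrl, btz)
    expect_lt(ht$p.value, 0.01)
    same <- comparePeaks(c(10, 11, 12), c(10, 11, 12))
    expect_equal(same$p.value, 1)
    expect_error(comparePeaks(100, c(90, 95)), "at least 2 vials")
    # peak vial values come from the group-mean peak day
    tc <- simulateTimecourse(0:4, 500, 3, peakDay = 1, noiseCv = 0,
                             nVials = 3L)
    expect_equal(unname(peakVialValues(tc)), rep(500, 3))
})
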