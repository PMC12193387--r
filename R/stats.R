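# Group-comparison statistics. The slope-equality "ANCOVA" is the F-test of
# the time x group interaction in a pooled OLS model of ln-fluorescence on
# time — the classic are-the-slopes-equal test.

# Guard an F ratio against a zero-residual (degenerate) model: with zero
# residual variance the F statistic is 0/0. Convention: no effect -> F = 0,
# p = 1; a real effect with zero residuals -> p = 0. Flagged via `degenerate`.
degenerateF <- function(termMs, residMs, scale) {
    eps <- 1e-12 * max(scale, 1)
    if (residMs > eps) return(NULL)
    if (termMs <= eps) list(F = 0, p = 1) else list(F = Inf, p = 0)
}

#' Test equality of decay slopes across groups (ANCOVA)
#'
#' Pools the windowed (time, ln fluorescence) points of all groups and fits
#' `ln_fluorescence ~ time * group` by OLS; the p-value is the F-test of the
#' `time:group` interaction. For two groups this is the classic ANCOVA test
#' of equal regression slopes. Use [windowedLnPoints()] to build each
#' group's points so the compared slopes are the reported ones.
#'
#' @param datasets named list; each element a data.frame with columns `time`
#'   and `ln_fluorescence` (one group's windowed points).
#' @return List with `slopes` (per-group OLS slopes), `interactionF`,
#'   `pValue`, `df` (numerator, denominator), `degenerate` (TRUE when the
#'   pooled model has zero residual variance, in which case the p-value is
#'   the documented 0/1 convention), and `nComparisons`.
#' @examples
#' g1 <- data.frame(time = 0:3, ln_fluorescence = 2 - 0.2 * (0:3))
#' g2 <- data.frame(time = 0:3, ln_fluorescence = 2 - 0.4 * (0:3))
#' compareSlopesAncova(list(a = g1, b = g2))$pValue  # ~0, degenerate
#' @export
compareSlopesAncova <- function(datasets) {
    if (length(datasets) < 2L) stop("need at least 2 groups")
    if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
        names(datasets) <- paste0("group", seq_along(datasets))
    for (g in names(datasets)) {
        d <- datasets[[g]]
        if (!all(c("time", "ln_fluorescence") %in% names(d)))
            stop("group '", g, "': needs columns time, ln_fluorescence")
        if (nrow(d) < 3L)
            stop("group '", g, "' has fewer than 3 points in its window")
    }
    pooled <- do.call(rbind, lapply(names(datasets), function(g)
        data.frame(datasets[[g]], group = g)))
    pooled$group <- factor(pooled$group)
    fit <- stats::lm(ln_fluorescence ~ time * group, data = pooled)
    # a zero-residual fit triggers a spurious anova() warning; the degenerate
    # case is handled explicitly below
    an <- suppressWarnings(stats::anova(fit))
    ia <- "time:group"
    Fv <- an[ia, "F value"]; p <- an[ia, "Pr(>F)"]
    degen <- FALSE
    dg <- degenerateF(an[ia, "Mean Sq"], an["Residuals", "Mean Sq"],
                      stats::var(pooled$ln_fluorescence))
    if (!is.null(dg)) { Fv <- dg$F; p <- dg$p; degen <- TRUE }
    slopes <- vapply(datasets, function(d)
        unname(stats::coef(stats::lm(ln_fluorescence ~ time, d))[2]),
        numeric(1))
    list(slopes = slopes, interactionF = Fv, pValue = p,
         df = c(an[ia, "Df"], an["Residuals", "Df"]), degenerate = degen,
         nComparisons = choose(length(datasets), 2))
}

#' Compare two collections of half-life values
#'
#' Unpaired two-tailed t-test on half-life values pooled across experiments.
#' Welch's unequal-variance form is the default (between-experiment variance
#' is rarely equal); `pooled = TRUE` gives the classic equal-variance test.
#'
#' @param groupA,groupB numeric half-life vectors (each of length >= 2).
#' @param pooled use the pooled-variance (Student) form.
#' @return An `htest` object (see [stats::t.test()]).
#' @export
compareHalflivesTtest <- function(groupA, groupB, pooled = FALSE) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("need at least 2 half-life values per group")
    stats::t.test(groupA, groupB, var.equal = pooled)
}

#' Two-factor ANOVA of half-life on age and sex
#'
#' Fits `half_life ~ age_group * sex` by OLS and runs sequential (Type-I)
#' ANOVA — the base-R `anova(lm(...))` behaviour. With a balanced design the
#' sequential and Type-II sums of squares coincide.
#'
#' @param table data.frame with columns `half_life`, `age_group`, `sex`
#'   (e.g. from [simulateHalflifeTable()]); both factors need >= 2 observed
#'   levels and every (age, sex) cell at least one row.
#' @return The ANOVA table (`anova` data.frame with rows `age_group`, `sex`,
#'   `age_group:sex`, `Residuals`). In the degenerate all-equal-response
#'   case, F is reported as 0 and p as 1 (flagged via the `"degenerate"`
#'   attribute).
#' @export
halflifeAnova <- function(table) {
    need <- c("half_life", "age_group", "sex")
    if (!all(need %in% names(table)))
        stop("table needs columns half_life, age_group, sex")
    table$age_group <- factor(table$age_group)
    table$sex <- factor(table$sex)
    if (nlevels(table$age_group) < 2L || nlevels(table$sex) < 2L)
        stop("each factor needs at least 2 levels")
    if (any(table(table$age_group, table$sex) == 0))
        stop("empty (age, sex) cells make the interaction unidentifiable")
    fit <- stats::lm(half_life ~ age_group * sex, data = table)
    an <- suppressWarnings(stats::anova(fit))
    degen <- FALSE
    for (term in setdiff(rownames(an), "Residuals")) {
        dg <- degenerateF(an[term, "Mean Sq"], an["Residuals", "Mean Sq"],
                          stats::var(table$half_life))
        if (!is.null(dg)) {
            an[term, "F value"] <- dg$F
            an[term, "Pr(>F)"] <- dg$p
            degen <- TRUE
        }
    }
    attr(an, "degenerate") <- degen
    an
}

#' Compare peak expression between two groups
#'
#' Unpaired two-tailed t-test on the per-vial fluorescence at the peak day —
#' the peak-level comparison (e.g. control vs proteasome-inhibitor flies).
#'
#' @param peaksA,peaksB per-vial peak-day fluorescence values (>= 2 vials
#'   each).
#' @return An `htest` object.
#' @export
comparePeaks <- function(peaksA, peaksB) {
    if (length(peaksA) < 2L || length(peaksB) < 2L)
        stop("need at least 2 vials per group for a peak comparison")
    stats::t.test(peaksA, peaksB)
}

#' Per-vial fluorescence at the peak day
#'
#' @param tc a [GroupTimecourse-class].
#' @return Named numeric vector: each vial's mean fluorescence on the day
#'   the group mean peaks.
#' @export
peakVialValues <- function(tc) {
    stopifnot(is(tc, "GroupTimecourse"))
    peak <- which.max(groupMean(tc))
    stats::setNames(tc@vialMeans[, peak], rownames(tc@vialMeans))
}
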