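---
title: "Measuring fluorescent-protein half-life in free-moving flies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fluorescent-protein half-life in free-moving flies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyTurnover)
```

## The measurement

A pulse of fluorescent reporter (eGFP, DsRED, mCherry, ...) is induced in
adult flies with a drug-switchable expression system. Once the drug is
withdrawn and synthesis stops, whole-animal fluorescence F declines in
proportion to degradation of the reporter. Under first-order kinetics,

$$F(t) = F_0 \, e^{bt}, \qquad b < 0,$$

so $\ln F$ is affine in time and the half-life is
$t_{1/2} = \ln 2 / |b|$. The package estimates $b$ by ordinary least
squares of $\ln F$ on $t$ over the segment from the expression **peak** to
the **subsequent minimum**, and converts with `halfLifeFromSlope()`. The
same machinery applies to three data scales: daily in vivo video (days),
per-fly microscope images (days), and in vitro plate-reader kinetics
(minutes); the time unit is carried explicitly in every `DecayFit` and never
converted silently.

Key assumptions: decay is single-compartment first-order over the fitted
window; fluorescence is proportional to protein amount (no detector
saturation — assays are run in the linear range); background is minimized
experimentally (dyed media, black filter paper) rather than subtracted
computationally.

## From video frames to a time course

Each vial is filmed by **two** synchronized cameras (different projections
of the same animals). Per frame, fly pixels are those

* inside the rectangular ROI (the vial),
* not excluded by an optional binary mask (e.g. a patch of background
  autofluorescence), and
* with raw intensity **strictly greater** than the detection threshold θ.

Candidate pixels are grouped into **8-connected** components; components
with at least `minBlobPx` pixels count as flies, and total fly fluorescence
is the sum of raw intensities over their pixels. Two conventions deserve
note, because threshold-based detection can be specified either way:

* the comparison is strict (`> θ`), chosen once and used identically in the
  per-pixel detector and everywhere a threshold appears;
* summation is over thresholded pixels themselves (no dilation to a fly
  "area", no background subtraction), which keeps the quantity exactly
  reproducible by a brute-force per-pixel oracle — the equivalence is tested
  on hundreds of random frames.

`minBlobPx` defaults to 1, so object-size filtering never changes totals
unless explicitly requested.

The two camera streams are combined by **summing** per-frame totals. The
choice of sum over mean is immaterial for the science: the log transform
turns a constant factor into an intercept shift, leaving the slope — and
hence the half-life — unchanged. After merging, frames whose combined total
is at or below the signal threshold are dropped (frames where flies were
poorly visible); the filter acts on the merged value, not per camera — the
alternative convention exists in older tooling, and the merged-value choice
is deliberate and documented here. Surviving frame totals average into one
value per vial per day; vials aggregate into a per-day group mean and sample
SD (n − 1). Days on which every frame was filtered yield an explicit
"no signal" missing value, which is excluded from fitting — imputing zero
would make the log transform meaningless.

## Window selection and fitting

The fitted window runs from the global maximum of the group mean (earliest
on ties) to the global minimum over the strictly later points (earliest on
ties). Interior bumps are retained — no monotonicity pruning — which matches
fitting a plain regression over a chosen range. If the series keeps rising
to the last day there is no decay window and the fit refuses to proceed. A
plateau that ticks up at the end still yields the global post-peak minimum;
treating the last recorded day as the minimum instead is a documented
alternative (pass `window` to `fitDecay()` explicitly).

Within the window, non-positive values are dropped with a warning before
taking logs; an epsilon offset would bias the slope downward and is never
applied. A non-negative fitted slope produces a fit whose half-life is `NA`
("undefined"), not a large fabricated number. Fits use the group means by
default; per-vial fits are available (`fitTimecourse(tc, perVial = TRUE)`)
but in practice offer no advantage in separating groups, so means remain the
default unit of analysis — including for the ANCOVA below, which consumes
the same windowed ln points the fit uses (`windowedLnPoints()`), so the
tested slopes are the reported slopes.

## Group comparisons

* **Equality of decay slopes** — `compareSlopesAncova()` pools the windowed
  ln points and fits `ln F ~ time * group`; the p-value is the F-test of
  the interaction. With two groups this is the classic ANCOVA
  "are-the-slopes-equal" test. A perfect (zero-residual) fit makes the F
  ratio 0/0; the implementation flags this and reports p = 1 when the
  interaction sum of squares is also zero, p ≈ 0 otherwise.
* **Accumulation** — `computeAUC()` integrates the group mean over the full
  day grid with the trapezoid rule; `aucFoldChange()` reports the treated /
  control ratio (e.g. proteasome inhibition raises both peak and AUC, while
  a translation inhibitor lowers them without changing half-life).
* **Half-life collections and peaks** — unpaired two-tailed t-tests.
  Welch's form is the default, since variance differs across experiments;
  the pooled form is available for textbook reproduction.
* **Age and sex** — `halflifeAnova()` fits `half_life ~ age_group * sex`
  and runs sequential (Type-I) ANOVA, the base-R `anova(lm(...))`
  behaviour. Balanced designs make Type-I and Type-II coincide (asserted
  numerically in the tests against an independent Type-II computation).
  The all-equal-responses degenerate case reports F = 0, p = 1, flagged.

No multiple-testing correction is applied anywhere; reports annotate the
number of comparisons so users can correct if their design calls for it.

## The synthetic experiment generator

`simulateVideoExperiment()` emulates the study conditions: 6 flies per
vial, 4 replicate vials, 2 cameras, 30 fps, daily recordings over 6 days,
fluorescence peaking one day after induction ends and decaying with a
programmed half-life (3.5 days by default). Flies are uniform-intensity
disks doing a reflected Gaussian random walk inside the vial ROI; the two
cameras are independent position realizations, because the pipeline only
sums intensities and never triangulates. Disks are kept non-overlapping so
the rendered blob total is exactly `nFlies × diskArea × intensity(day)` —
the ground truth is analytic, which is what makes the noiseless
pipeline-equals-truth tests exact. Per-pixel Gaussian noise is added and
clipped at zero (detector counts cannot be negative); frames persist as
16-bit grayscale TIFF sequences with a manifest, because video codecs are
lossy and nondeterministic.

Parameters the assay itself does not pin down are free choices, made once:
64×64-pixel frames, background 50 AU, fly peak intensity 10000 AU, noise SD
200 AU (2% of peak; validation runs use 500 AU = 5%), random-walk step SD
2 px/frame. Recording length defaults to 30 frames (one second of video):
per-frame totals are i.i.d. around the daily value, so a short clip
estimates the daily mean to well under a percent — the full 4-minute
recordings of a real experiment buy robustness to fly behaviour, not
statistical precision of this simulator. The companion generators are
`simulatePlateSeries()` (decay in minutes, 30-s sampling, multiplicative
lognormal noise), `simulateTimecourse()` (vial-level daily values directly,
skipping the video layer — used for statistical power/size validation), and
`simulateHalflifeTable()` (balanced age × sex tables from a two-factor
linear model).

What the simulator does **not** emulate: real fly shape and gait, uneven
illumination across the vial, occlusion and camera-coverage gaps,
autofluorescence structure, photobleaching, or day-to-day biological
variation in expression. Passing the recovery tests therefore demonstrates
that the analysis chain is correct and unbiased under its stated model, not
that any particular recording rig meets that model.

## Validation problem sizes

The test suite validates, among others: exact noiseless identities
(halving series → slope −ln 2; ground-truth equality of quantified totals);
oracle equivalence of the frame quantifier on 500 random frames ≤ 32×32
with random ROI/mask/threshold; end-to-end recovery of a 3.5-day half-life
within 15% across 100 simulated 4-vial, 6-day experiments at 5% pixel
noise; ANCOVA power ≥ 80% for 3.5 d vs 17 d and type-I error within
[0.02, 0.09] at α = 0.05 over 1000 null simulations (6 points/group, 10%
multiplicative noise); and ≥ 95% detection of a 5-residual-SD age effect
in 200 simulated half-life tables (n = 10/cell). `scripts/acceptance.R`
recomputes these quantities from scratch at the same sizes.

## Known limitations

* Window selection keys on the group-mean maximum; with very slow decay and
  noisy data the empirical peak can drift into the series, shortening the
  window. Supplying the window explicitly is the remedy.
* The ANCOVA treats time points as independent; serial correlation within a
  vial across days is not modelled (no mixed-effects machinery).
* Object counts from the two cameras are summed, not de-duplicated — they
  are a per-stream detection diagnostic, not a census of flies.
* Only single-channel frames are quantified; colour captures must pass
  through `extractChannel()` first (green for GFP-class, red for
  DsRED/mCherry-class reporters).
* Intensities written to disk are 16-bit counts; AU above 65535 per pixel
  cannot be stored losslessly and are rejected rather than rescaled.
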