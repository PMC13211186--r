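---
title: "Image-based oocyte morphometrics for zebrafish IVM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based oocyte morphometrics for zebrafish IVM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmorph)
```

## The measurement problem

Zebrafish oocyte in vitro maturation (IVM) assays depend on selecting
stage III (late vitellogenic) follicles before induction, and on measuring
each oocyte's diameter before and after incubation. Stage is operationally
defined by diameter: stage III spans roughly 340–690 µm, with stage IV
(690–730 µm) and stage V (730–750 µm) immediately above; sorting uses a
stricter 550–690 µm window to isolate late vitellogenic follicles and avoid
stage overlap. The two assay endpoints are the germinal vesicle breakdown
(GVBD) rate — a human-scored binary call per oocyte — and the per-oocyte
diameter change Δ = D~final~ − D~initial~, both summarised at the culture
dish level (the experimental unit, typically 3 dishes × 30 oocytes per
group).

`ivmorph` implements the computational portion of this workflow: circle
detection in bright-field-like frames, multi-frame consistency and overlap
QC, stage-micrometer calibration, diameter-based selection, manual-correction
accounting, endpoint summaries and the dish-level statistics. GVBD is
deliberately *never* inferred from images — it is scored by a person under a
stereomicroscope and enters the pipeline as data. Automating that call would
change the assay, not reimplement it.

## Detection: a gradient-voting circle Hough transform

The detector is implemented as a described operator rather than delegated to
an off-the-shelf routine, so that every stage of it can be validated against
generator ground truth:

1. **Gradients.** One pass of separable binomial smoothing, then 3×3 Sobel
   kernels give the gradient field; magnitudes are normalised to grey levels
   per pixel so thresholds have physical units.
2. **Edges.** Hysteresis thresholding (defaults: low 10, high 30 grey/px)
   keeps pixels above the low threshold that are 8-connected to a pixel
   above the high threshold. For a rim rendered with a 2 px linear ramp the
   peak gradient approximately equals the disk contrast, so the default high
   threshold admits disks with contrast ≳ 30 grey levels.
3. **Voting.** For each radius r in the search range, every edge pixel votes
   at ±r along its gradient direction into a centre accumulator (optionally
   downscaled). Votes are pooled over 3×3 cells and normalised by 2πr, the
   theoretical vote count of a complete rim, giving a score in [0, 1].
4. **Peaks.** Pooled local maxima with score ≥ `accumulator_threshold`
   (default 0.3) become candidates; candidates closer than
   `min_center_dist_px` (default `r_min_px`) collapse to the
   highest-scoring one, with deterministic tie-breaks (lower y, then lower
   x, then smaller radius).
5. **Verification and refinement.** Each candidate must have radially
   oriented edge support covering at least half of its circumference
   (36 sectors of 10°). This rejects the classic failure mode of gradient
   voting, where an arc of a large rim votes like a small tangent circle.
   Survivors are refined to sub-pixel centre and radius by an algebraic
   (Kåsa) least-squares circle fit on their rim support; the fit is
   discarded if it drifts more than 3 px from the accumulator estimate.

The radius search range is the user-defined selection window converted to
pixels with the current calibration, plus a margin. On seeded synthetic
scenes (1–8 non-overlapping disks, contrast ≥ 50, noise SD ≤ 5) the test
suite requires recall and precision ≥ 0.95 with centre and radius errors
≤ 2 px; the achieved errors are typically well under 1 px after refinement.

Raising `accumulator_threshold` can only remove candidates, and greedy
suppression processes candidates in score order, so the number of detections
is non-increasing in the threshold — a property the tests check directly.

## Temporal consistency, overlap filtering and the correction ledger

Live sorting views the same field over consecutive frames. Detections are
linked frame-to-frame by greedy nearest-centre matching (a detection joins
the nearest open track within `match_tol_px`, default `max(5, 0.1·r_min)`,
if the radius agrees within 20%); a track is *confirmed* when it is present
in at least `k_min` consecutive frames (default 3). On small instances the
greedy linker is tested against exhaustive optimal assignment, and the
confirmation rule against a brute-force longest-run oracle. Greedy,
score-ordered overlap suppression then discards any circle whose centre
falls inside a kept circle or closer than half the summed radii; the
operation is idempotent and never increases the count.

Operator corrections — adding a missed oocyte, removing a false positive —
are recorded in a ledger. The QC metric is the manual correction rate

$$\mathrm{rate} = \frac{N_\mathrm{manual}}{N_\mathrm{auto} + N_\mathrm{manual}} \times 100\%$$

where `N_auto` counts automatic detections *retained after removals* and
`N_manual` counts interventions of both kinds. The accounting convention for
removed false positives is not uniquely determined by the formula's usual
presentation; counting removals in the numerator (and excluding them from
`N_auto`) keeps the denominator equal to the final-responsibility set and
reproduces both published endpoint values, 5.26% (1 manual, 18 auto) and
26.67% (4 manual, 11 auto). Both counts are configurable inputs to the
ledger rather than hard-coded behaviour.

## Calibration

A stage micrometer imaged at each magnification provides the pixel scale.
The mean intensity profile perpendicular to the rulings is searched for
prominence-filtered minima; each line is localised to sub-pixel precision by
parabolic interpolation through the three profile samples around the
minimum. The known cumulative distance (i − 1)·spacing is then regressed on
detected position: the slope is µm/px, the intercept merely absorbs the
phase of the first ruling, and the RMS residual (in µm) is reported as a
quality figure. Only one physical parameter is estimated — lens distortion
or spatially varying scale is out of scope, matching how a single conversion
factor per magnification is used in practice. On noiseless synthetic targets
the round trip recovers the scale to better than 10⁻⁶ relative error; with
±0.5 px uniform line jitter it stays within 1%.

The synthetic micrometer renders rulings with a Gaussian intensity profile
(σ = half the nominal line width) rather than hard rectangles: a sampled
symmetric profile makes parabolic localisation well-posed, while a flat-
bottomed rectangle would leave the interpolation degenerate. Ruling spacing
is a required input — there is no universal default pitch.

## Staging and endpoints

Stage windows are half-open `[lo, hi)` so that a boundary diameter belongs
to exactly one stage (690 µm is stage IV, not III; 730 µm is stage V); the
uppermost window is right-closed so 750 µm still classifies. The broad and
strict stage III definitions are kept as two separate non-overlapping
schemes (`stage_windows("broad")`, `stage_windows("strict")`) because a
single map containing both would be ambiguous for any diameter in
550–690 µm.

Per-oocyte Δdiameter requires both measurements; oocytes lost before
re-measurement are excluded from the dish mean Δ (their ids are reported)
but still count in the GVBD denominator when scored. Dish summaries are
permutation-invariant, and a loader warning fires when a dish deviates from
its declared size.

## Statistics

The dish-level pipeline mirrors standard practice for this assay: per-group
Shapiro–Wilk normality checks and Levene's test (one-way ANOVA on absolute
deviations from the group mean; median-centred variant available), then an
unpaired pooled-variance t test for two groups or one-way ANOVA followed by
Fisher's LSD for more. Paired t on pre/post diameters of the same oocytes is
provided for within-group comparisons. Standard tests are delegated to R's
`stats` machinery (`shapiro.test`, `t.test`, `anova(lm(...))`); LSD, which
has no base-R implementation, uses the pooled ANOVA mean square error with
the within-group degrees of freedom and **no multiplicity adjustment** — that
is the definition of LSD, and it is stated prominently rather than hidden.
Pairwise LSD results are always computed for auditability but flagged
`gated` (not interpretable) unless the omnibus ANOVA is significant at
α = 0.05. Assumption-check failures raise warnings; no automatic
nonparametric fallback is applied, because the analysis plan being
reimplemented specifies none.

Fixtures pin the suite to an independent reference implementation (Shapiro W
and p, Levene F and p to 10⁻⁶), to hand-computed values (paired t = 5.0 on
differences (1, 2, 2); F = 3.0 on a three-group fixture), and to algebraic
identities (two-group F = t² to 10⁻⁹). Simulation checks calibrate the
pipeline: under the null at the study design size (6 groups × 3 dishes) the
empirical type-I error over 2000 datasets must lie in [0.03, 0.07], and a
3×SD group shift must be detected in at least 80% of 500 simulated
experiments.

## The synthetic generator: what it emulates, and what it does not

The generator stands in for the live microscope feed: bright background
(default grey 200) with darker anti-aliased disks (linear rim ramp, default
2 px), signed per-circle contrast, i.i.d. Gaussian pixel noise, per-frame
Gaussian centre jitter with fixed radii, and ruled micrometer targets.
Coordinates are 0-based pixel-centre throughout; images are 8-bit by default
with 16-bit supported. Everything is seeded and bit-reproducible, and every
scene carries exact ground truth.

It deliberately does **not** model yolk granularity, the germinal vesicle,
optical point-spread, illumination gradients, debris, or touching/deformed
oocytes. Passing the recovery tests therefore demonstrates correctness of
the detection machinery on well-posed circular objects — not robustness to
every real-world imaging pathology. The manual-correction ledger exists
precisely because real frames are harder than synthetic ones.

Defaults for the simulated experiment follow the study design: six groups
(hormone-free control, DHP positive control, DHP + BTBPE at 1, 10, 100 and
1000 nM), 3 dishes × 30 oocytes, initial diameters from a normal
(mean 620, SD 30 µm) truncated to the 550–690 µm window, and incubation
endpoints drawn per group. The group effect sizes (GVBD probabilities
0.05 / 0.85 / 0.45 / 0.55 / 0.65 / 0.35; mean Δ of 2 / 20 / 8 / 10 / 14 / 6 µm
with 8 µm per-oocyte SD) are the package's own choices: the corresponding
published results are reported only graphically, so these values were fixed
once at magnitudes a practitioner would consider realistic — strong DHP
induction, near-zero spontaneous maturation, and clearly suppressed but
non-monotonic dose responses — and are not tuned to reproduce any particular
figure.

## The end-to-end pipeline

`run_pipeline()` executes calibrate → detect → temporal QC → diameter
selection → (ingest GVBD scores) → summarise → statistics on a simulated
experiment. Each dish is laid out on a non-overlapping grid and imaged at
8 µm/px (a coarse but fast scale chosen so the full 18-dish design renders
and detects in about a minute and a half; sub-pixel radius refinement keeps
diameter errors to a few µm at this scale), with a 3-frame jittered sequence
before incubation and a single frame after. Detector misses and false
positives relative to ground truth are converted into the manual
additions/removals an operator would perform, so the correction ledger and
rate are exercised meaningfully. All artifacts (calibration, oocyte table,
QC report with diameter histogram and per-dish correction rates, dish
summaries, statistics report, log) carry the configuration hash and contain
no timestamps, so a rerun with the same config and seed reproduces
byte-identical outputs — a property the acceptance suite asserts at full
design scale.

## Numerical choices and degenerate inputs

* Micrometer values are serialized at 0.1 µm precision; sub-pixel noise
  below that is below measurement meaning.
* Degenerate statistics inputs error early with informative messages (n < 3
  for Shapiro–Wilk, zero variance everywhere for ANOVA, unequal-mean
  zero-variance t inputs); the one deliberate convention is t = 0, p = 1
  for identical groups with zero pooled variance.
* Levene's test on groups whose absolute deviations are all equal returns
  F = 0, p = 1 rather than failing on the degenerate ANOVA.
* Empty scenes, blank images and empty histograms are valid inputs with
  well-defined empty outputs; a blank calibration image errors with advice
  to re-image.
* Jittered sequence centres are clamped to the image bounds rather than
  rejected, since a frame-edge excursion is not an invalid scene.

## Known limitations

Ellipse fitting, deformable contours, overlap-heavy colonies, GPU paths,
lens-distortion correction and live camera capture are out of scope. The
Hough accumulator quantises radii at `radius_step_px`; the Kåsa refinement
recovers sub-pixel values but inherits a small inward bias (≲ 1 px) from
edge-band asymmetry, which cancels in Δdiameter comparisons at matched
scale. The statistics module implements the analysis plan it reimplements —
including its lack of multiplicity correction beyond the ANOVA gate — and is
not a general-purpose inference toolbox.
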