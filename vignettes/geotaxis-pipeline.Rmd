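---
title: "Methods: automated analysis of tap-and-climb geotaxis assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated analysis of tap-and-climb geotaxis assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and what the package computes

Negative geotaxis is the innate escape response of *Drosophila*: flies
knocked to the bottom of a vial climb back up. In the rig this package
targets, a rack of 12 vials sits in front of a light background, a lever
taps the rack to ground the flies, and a fixed camera records at 60 frames
per second, 1280 x 720 pixels. One recording holds four tap-pause cycles;
each 15-second pause is one climbing trial ("trim"), treated as a technical
replicate. A vial of ~25 same-sex, same-genotype flies is the biological
replicate.

`geotaxr` turns such a recording (or a synthetic equivalent) into
statistics in five stages, mirroring the module layout of `R/`:

1. **Trial splitting** (`build_movement_trace()`, `find_trials()`): a
   per-frame motion energy is computed and tap spikes mark trial
   boundaries.
2. **Vial localisation** (`detect_vials_rule_based()`,
   `filter_sort_match()`): vial bounding boxes are detected, matched to
   the metadata table, and written to CSV.
3. **Fly tracking** (`track_trim()`): per-frame centroids with vial and
   LP/MP/HP zone assignment, converted to physical units.
4. **Aggregation** (`collect_experiment()`): sex-split, replicate-labelled
   wide tables for position, velocity and the three zone occupancies.
5. **Statistics** (`fit_lme()`, `harmonic_mean_p()`, `mwu_timepoints()`,
   `mwu_peaks()`, `comparison_report()`).

## Trial splitting

Motion energy of a frame is the summed area (px²) of connected
foreground regions of at least 2,000 px², where foreground means an
absolute difference from a background model above a grey-level threshold
(default 25). The background model is a running average updated with
weight 1/500 per frame — a deliberately simple, fully deterministic model;
a Gaussian-mixture model would serve the same role and the
`frame_motion_energy()` interface accepts any background image.

A tap spike is a local maximum of the trace at or above 100,000 movement
units. A trial starts at the first frame after the spike whose energy
falls below 30,000 units, and ends with the first run of at least 270
consecutive sub-threshold frames — at the end of that run, at
`start + 900` frames, or at the next spike, whichever comes first. The
start rule (first quiet frame) aligns trial time zero with the end of
tapping; the end rule is one of two defensible readings of "an end frame
is defined by a 270-frame inactivity run", and is pinned down by a
brute-force oracle in the test suite. If more than the expected four
trials emerge, the four following the highest spikes are kept; fewer
trials proceed with a warning.

## Vial localisation

The shipped detector is rule-based and deterministic: vials read as pairs
of tall dark vertical strips (the vial walls) against the light
background. Columns whose dark-pixel count reaches half the tallest
column's are wall candidates; consecutive candidates merge into strips;
strips pair left-to-right into boxes. Confidence is the fraction of
wall-strip rows that are dark. Detections below confidence 0.85 are
dropped, survivors are sorted by `x1` and numbered positionally (leftmost
= vial 1), and positions absent from the metadata are discarded. The
positional rule is the only correspondence the assay defines; it is
fragile if the rack is loaded with gaps, which is why
`filter_sort_match()` errors loudly when fewer confident detections than
metadata rows survive.

Any learned detector can stand behind the same interface: `run_pipeline()`
accepts an arbitrary `frame -> detections` callable, and
`evaluate_detector()` scores it by greedy highest-IoU matching against
ground truth (unmatched truth scores 0). Boxes are pixel rectangles with
origin top-left, y increasing downward, half-open on both axes — the
convention every containment and IoU computation in the package shares.

## Fly tracking and zoning

The trim background is the per-pixel **maximum** of the red channel over
all trim frames: flies are transient dark blobs, so the maximum recovers
the empty scene. Each of the first 780 frames is subtracted from the
background, and the clipped difference is binarised with separate
thresholds for the upper (0.12) and lower (0.18) image halves — the lower
half of the chamber sits farther from the light source, so a higher
threshold suppresses its stronger residual texture. The thresholds are
exposed configuration, validated on synthetic scenes. Connected
components within 4–400 px² yield centroids; the band rejects
single-pixel noise and merged multi-fly clumps. Fly identity is *not*
tracked across frames — the assay counts centroids per frame, so
occlusion merging costs a count, never corrupts a trajectory.

Each centroid is assigned to the vial whose box contains it (half-open
containment; overlap ties go to the smaller `x1`) and zoned by its height
above the vial bottom: LP below one third of the vial height, HP at or
above two thirds, MP between. The thirds are a symmetric default — the
assay defines the zones but not the fractions — and are configurable
(`lp_frac`, `mp_frac`). During the first 60 frames, centroids within 10%
of the vial height from the top are suppressed: flies cannot have climbed
there yet, so such blobs are artefacts not yet fully in view (the
"adder" guard; both magnitudes are configuration, not measured
constants).

Height in cm is `17 * adj / 720` — the 17 cm chamber height imaged over
720 rows — where `adj` is the centroid's pixel height above the vial
bottom after any configured per-vial offset (default 0). Time in seconds
is `frame / 60`. Summaries subsample every 30th frame (2 Hz), giving 26
time points over the 780-frame window; zone percentages use detected
flies as the denominator, so populated time points always sum to 100%
(metadata N would not guarantee that, since detection counts fluctuate).
The four trims aggregate as mean ± SEM; a time point backed by a single
trim reports SEM 0 with a warning rather than losing its row.

## Aggregation and velocity

Replicate labels are `<Genotype>_rep<N>`, with `N` counting prior
occurrences of the genotype *within the same sex across all folders*,
folders sorted lexicographically so labels are stable across reruns.
Velocity is the numerical gradient of climbing height against the actual
time grid — central differences inside, one-sided at the ends — computed
per replicate *before* any averaging. Recordings with different time
grids merge on the union with missing cells left `NA`; no interpolation
is invented.

## Statistics

For each sex and modality the wide table is melted to long form and
restricted to the control genotype, the chosen comparisons, and
`time <= Tmax`. The mixed model is

```
value ~ genotype * time_cat + (1 + time | subject)
```

fitted by REML with `lme4`. Time enters the fixed effects categorically
and the per-subject random structure numerically (random intercept and
time slope) — the dual use is intentional: categorical time makes no
shape assumption about the climbing curve, while the numeric random slope
captures each vial's overall trend. Fixed-effect p-values are Wald z
tests (`2 * pnorm(-|est/se|)`); with ≥ 10 subjects per arm the normal
approximation is adequate, and the test suite checks the type-I error of
the genotype main effect at α = 0.05 stays within [0.01, 0.12] over 200
simulations from the model itself (20 subjects/arm, 5 time points,
between-subject sd 0.5, residual sd 0.3), with ≥ 95% power against a
5-residual-sd offset.

Each comparison genotype owns one main-effect p-value plus one per
genotype x time interaction; these are combined with the harmonic mean
p-value `min(1, r / Σ 1/(p_i + ε))`, ε = 1e-12. ε sits inside each
reciprocal because its only job is to guard `p_i = 0`; for any p-value
numerically above ~1e-9 its effect is nil. The HMP is conservative for
dependent tests, which these are. Singular or non-converged fits are
flagged and reported, not fatal — a batch of four comparisons should not
die on one degenerate modality.

Mann-Whitney U tests complement the model: two-sided, per time point
(rendered as −log10(p) heatmaps) and on per-replicate peak metrics (the
maximum of each replicate's series within the window). The exact null
distribution is used when the combined sample size is ≤ 20 with no ties;
otherwise the normal approximation with continuity and tie correction.
All-identical inputs return p = 1 by convention. No multiple-testing
correction is applied across the per-timepoint grid — none is defined for
this assay's report format, and the HMP is the only combination step; the
grid is read as a descriptive map of *when* genotypes diverge, not as a
family of confirmatory tests.

`comparison_report()` assembles the standard 10-row table (five
modalities × {LME-HMP, peak-MWU}, cells `"p (stars)"`, stars `***`/`**`/
`*` at 0.001/0.01/0.05 inclusive), the trajectory plot with SEM bands,
the −log10 HMP bar panel, and the heatmap.

## The synthetic scene generator

`render_recording()` emulates the rig: grey-255 background, vials drawn
as pairs of dark walls, flies as filled dark blobs (5 px radius at full
resolution), four tap bursts — 5 frames of whole-frame jitter plus blob
displacement, which is what the splitter's spike detection keys on —
each followed by 900 climbing frames. Flies start spread over the bottom
15% of the vial, carry a persistent per-fly base speed (default 0.8 ±
0.15 cm/s, putting a healthy cohort near 10 cm after 13 s) plus
per-frame jitter and a 5% stall probability. A single scene seed fans out
into per-fly and per-frame substreams, so rendering is bit-identical
given the configuration, frame-by-frame, in any access order.

What the generator does *not* emulate: glare, condensation, shadows,
uneven illumination, wing posture, walking on the vial walls in depth,
or flies descending after topping out. Passing tests on synthetic scenes
therefore demonstrate that the algorithms implement their contracts
(correct thresholds, windows, conversions, statistics), not that the
detector or tracker is robust to every artefact of laboratory video.

The series-level scenario generator `synth_dissociation_tables()`
emulates the dissociation phenotype of a mutant that climbs normally but
cannot sustain height: both cohorts follow the saturating climb law
`y(t) = plateau (1 − e^{−t/τ})` (plateau 10 ± 1 cm, τ = 5 s, so
instantaneous velocity peaks near 2 cm/s at the start and decays
identically for both genotypes), and after a staggered onset (8 ± 0.7 s)
the mutant loses 0.5 cm/s while the control holds its plateau. With 10
replicates per arm and 0.7 cm of per-timepoint measurement noise, the
position trajectory shows a clear late deficit while the velocity series
— whose signal is buried by differentiation noise — stays
non-significant. An earlier piecewise-linear draft was rejected because
it made the velocity *peak* a pure noise-maximum statistic and gave the
mutant a genuine sustained velocity deficit, contradicting the phenotype
being modelled.

## Numerical choices and degenerate inputs

- Boxes and coordinates: 0-based, half-open on both axes; a centroid on a
  shared edge belongs to the right-hand vial.
- Trial search: peak = local maximum with `v[i] > v[i-1]` and
  `v[i] >= v[i+1]`, so burst plateaus yield one spike; a spike with no
  subsequent quiet frame before the next spike yields no trial.
- SEM with n = 1 is 0 with a warning (keeps table shapes stable); SEM
  uses sd/√n.
- Zone boundaries tile the vial exactly: LP on `[0, H/3)`, MP on
  `[H/3, 2H/3)`, HP on `[2H/3, H]` in height-from-bottom.
- Rank-deficient fixed-effect designs (e.g. duplicated time levels) are
  handled by `lme4`'s column dropping; failed covariance computations
  degrade to NA p-values on a flagged fit.
- Empty inputs error early and loudly (`find_trials` on zero peaks is
  the one silent case: an empty segment list is a legitimate outcome).

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data,
at sizes chosen to exercise every contract while staying light: unit
tests use 2–6 vial racks at 320 x 180 with 10–150 frames; the detector
quality check uses 50 full-resolution 1280 x 720 frames; the tracking
window check uses a 900-frame trim (320 x 180 in tests, 640 x 360 in the
acceptance script) with `image_height_px` set to match, since every
counted quantity — 780 tracked frames, 26 time points at 2 Hz, 4 trials,
900-frame caps — is resolution-independent. Statistical calibration uses
200 null and 100 alternative simulations of the mixed model.

## Limitations

- The rule-based detector assumes upright, well-separated vials in front
  of a light background; heavy occlusion or glare defeats it. The
  detector hook exists precisely so a learned model can replace it.
- Centroid counting does not resolve occlusions; two touching flies are
  one centroid until they separate.
- Percent-occupancy denominators are detected flies, so frames where
  detection drops are noisier, not biased.
- The velocity tables differentiate noisy positions; their tests are
  conservative by construction, which is also why the assay's
  position/velocity dissociation is statistically meaningful.
- H264 decoding requires an external `ffmpeg`; frame directories are the
  native, dependency-free input format.
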