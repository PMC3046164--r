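---
title: "Second-order motion numerosity stimuli and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order motion numerosity stimuli and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numotion)
```

## The problem

Numerosity estimation — judging *how many* items a display contains without
counting — is confounded, in ordinary displays, with non-numerical quantities.
Adding a dot to a dot collection necessarily changes its spatial extent or its
density, so an observer (or a model) could produce accurate "numerosity"
estimates from luminance-based spatial statistics alone. The *occupancy*
family of models makes this concrete: perceived numerosity is predicted by the
area covered by the union of disk-shaped "influence spheres" centred on the
items, a pure function of the luminance-defined image.

`numotion` implements, in one tested package:

1. a stimulus generator in which a variable number of bars moves over a
   random-texel background either as **first-order** (luminance-defined,
   black) items or as **second-order** (contrast-defined) items that exist
   only as frame-to-frame polarity inversions of the background texture and
   carry *no* luminance signature in any single frame;
2. the occupancy model family — fixed-radius union-of-disks occupancy, the
   density-adaptive normalized variant, and the spatial-filtering route — so
   that the models' blindness to the second-order stimuli can be demonstrated
   computationally;
3. a simulated observer producing power-law estimates with scalar
   variability, and the analysis chain used on such estimate tables.

## Stimulus model

**Geometry.** The default display is 1024×768 pixels at 75 Hz viewed from
58 cm; at that distance one degree of visual angle subtends ≈30.77 pixels.
The background is a field of 4×4-pixel squares ("texels"), each independently
gray (128) or white (255) with probability 1/2, so the frame is a 256×192
texel matrix. Under this convention the 0.13° bar width is exactly one texel
column and the two bar heights (2.08°, 3.12°) are 16 and 24 texel rows.
Every geometric parameter is configurable through `display_geometry()`.

**Layout.** `sample_layout(n)` places `n` bars on a 17×12 imaginary grid by
seeded rejection sampling. The grid pitch (≈1.96° horizontally, 2.08°
vertically) guarantees the spacing rule — any two bars at least 1.84° apart
horizontally *or* at least 0.98° apart vertically, centre to centre — for
every pair of distinct cells, and a 1.84° margin is reserved at the right
screen edge so the motion never pushes a bar off screen. `verify_layout()`
re-checks every pair brute-force, independently of the sampler's
bookkeeping. Layout capacity is limited by the 204 grid cells (and in
practice slightly further by the motion margin and the bottom screen edge);
impossible requests raise a capacity error rather than looping forever.

**Motion.** The bars are visible for 133 ms — 10 frames at 75 Hz — during
which they move 1.84° to the right and back. The profile is the symmetric
ramp `1.84 × c(0:4, 4:0)/4`, snapped to whole texels (maximum 14 texels =
1.82°, within half a texel of the nominal excursion). The ramp was chosen so
that the offsets start and end at exactly zero and are unimodal; the exact
speed profile is a free design choice since only the total excursion and the
duration are constrained, and any monotone-up/monotone-down texel-snapped
profile preserves every property tested here.

**Second-order rendering.** `render_second_order()` follows the classic
polarity-inversion recipe: at each visible frame all texels inside each
bar's current footprint swap gray↔white, then the footprint moves to the
next offset. By default the texture state *persists* (a flipped texel stays
flipped until a footprint revisits it); `invert_mode = "fresh"` instead
flips relative to the untouched background each frame. Because gray and
white are exchangeable under the Bernoulli(1/2) texture, either way each
texel's marginal distribution in any single frame is exactly Bernoulli(1/2)
regardless of the layout: a single frame is distributionally independent of
numerosity, which is the property that removes all first-order cues. After
the visible epoch the untouched background reappears (the display's
background is visible throughout a session), for the first-order condition
identically so.

## Occupancy models

`union_disk_area()` rasterises the union of radius-`r` disks (or, for items
with extent, rectangles dilated by `r`) at 0.02°/cell by default;
`union_disk_area_mc()` is an independent Monte-Carlo estimate used as an
oracle in the tests (10⁶ samples by default). `durgin_estimate()` implements
the density-adaptive variant: the radius shrinks with density as
`r(d) = r0/(1 + k·d)` — a bounded, monotone law chosen because only the
monotonicity is established; `k` and the whole radius function are
pluggable — and the union area is normalized by the disk area `πr²` so that
`n` disjoint spheres score exactly `n`. `filter_occupancy()` is the
spatial-filtering route: the black-texel mask of a rendered frame is dilated
by a disk of radius `r` (equivalently, convolved with a binary disk kernel,
counting the strictly positive response) and the covered area is returned.

On first-order frames this filter response grows with numerosity; on
second-order frames the mask is empty and the response is identically zero
for every numerosity — the model family's blindness to contrast-defined
items, demonstrated computationally in `test-acceptance.R`.

## Simulated observer

Estimates follow `ψ = gain_cond · c · φ^n · exp(ε)` with `ε ~ N(0, σ²)` and
`σ = sqrt(log(1 + cv²))`, so repeated estimates at a fixed numerosity have a
constant coefficient of variation — *scalar variability* by construction —
then are rounded to integers with a floor of 1 (typed numeral responses).

Defaults (all configurable in `observer_params()`): `cv = 0.33`, a typical
human level for estimation beyond the subitizing range; `c = 1.9`,
`n = 0.8`, which over the 10–30 range give mild overestimation of small
numerosities shading into underestimation of large ones; condition gains
1.1 (first-order) vs 1.0 (second-order), making first-order estimates
uniformly higher. These reproduce the qualitative pattern expected of human
observers in the two motion conditions; the multiplicative-lognormal noise
family is the minimal model with constant CV, not an empirical claim about
the human noise distribution. Per-subject parameter jitter
(`subject_sd`) is available but off by default: the repetition noise already
produces realistic between-subject spread, and identical subjects make the
generator's calibration properties exactly computable. An optional
per-condition exponent offset reproduces a condition-by-numerosity
interaction; it too is off by default.

## Analysis chain

`scalar_variability_report()` computes, per condition and numerosity, the
group mean estimate and its standard error (SD of the subjects'
per-numerosity means over √subjects by default; a within-subject variant is
available), then

* the regression of log SE on log mean estimate — slope ≈ 1 under scalar
  variability, ≈ 0 under additive constant-SD noise;
* the linear SE-on-mean fit's adjusted R²;
* the pooled regression of per-(subject, numerosity) CVs on the
  numerosity's **group** mean estimate. The group mean, rather than the
  cell's own mean, is used as the regressor deliberately: a cell's CV and
  its own mean are computed from the same handful of draws, and that shared
  sampling noise alone produces a spurious R² of ≈0.014 under a perfectly
  flat CV, while against the group mean the average R² is the pure null
  rate (≈1/(cells−1) ≈ 0.004);
* per-numerosity bias t tests, reported uncorrected (with a Bonferroni
  column) since the corresponding claim is the *absence* of significant
  bias at any numerosity.

Cells with one observation are excluded from the CV analysis with a
warning; a noiseless table yields zero SEs and a degenerate (NA-slope)
report rather than an error.

`per_subject_regression()` regresses log estimate on log numerosity and log
mean bar height for one subject and condition, z-scoring all three log
variables so the coefficients are standardized (the standardization
convention is a package choice; published tables of this design do not
state theirs). The residual df is the standard `rows − 3`; note that
published per-subject tables of this design sometimes print `t(125)` for
126 trials, which the standard convention would make `t(123)`.

`rm_anova_2way()` collapses repetitions to cell means, log-transforms, and
computes the classical two-way within-subjects ANOVA by explicit balanced
sums of squares, testing each effect against its subject-interaction error
term, with partial η² = SS_effect/(SS_effect + SS_error). With 11 subjects
and a 2×21 design the df are (1,10) for motion order and (20,200) for
numerosity and the interaction. No sphericity correction is applied (the
reference analyses report uncorrected df); Greenhouse–Geisser adjustment is
out of scope. The implementation is cross-checked in the tests against both
`stats::aov` error strata and a brute-force sums-of-squares oracle (6-decimal
agreement).

`condition_correlation()` averages the repetitions of each numerosity within
condition and correlates the two conditions' 21 per-numerosity means for one
subject.

## Sessions

`build_schedule()` emits, per condition: 3 calibration trials at numerosity
20 with a feedback numeral flag, 40 practice trials with numerosities drawn
uniformly *with replacement* from 10–30 (the sampling mode is not otherwise
determined), and a seeded uniform permutation of the 21×6 experiment-proper
trials. Practice is run per condition by default (parallel to the
per-condition calibration) and conditions run as two blocks; both choices
have switches (`practice_per_condition`, `interleave_conditions`) because a
fully interleaved reading of the design is also defensible. The feedback
numeral is recorded as a schedule flag, not drawn into exported frames.
Every trial gets its own layout and texture seed derived from the master
seed, so trials are independent yet the session is bit-reproducible.

## Numerical choices and problem sizes

* Raster resolution 0.02°/cell for union areas (≤0.5% discretization error
  at the radii used here); Monte-Carlo oracle 10⁶ samples.
* The simulation studies in the tests and the acceptance script use the full
  design size (11 subjects × 2 conditions × 21 numerosities × 6 reps) with
  100 simulation seeds for averaged quantities — large enough that the
  Monte-Carlo error on the averaged slope is ≈0.02, small enough to run in
  seconds. Null calibration of the ANOVA uses 300 simulated null datasets on
  a reduced 2×8 design.
* Texel-marginal invisibility is tested with 200 texture seeds per layout;
  under the Bernoulli(1/2) exchangeability argument the property is exact,
  so the sample size only controls the power of the confirmatory test.
* Integer responses floor at 1; degenerate inputs (single numerosity,
  constant predictor, zero-variance condition, missing design cells) raise
  informative errors or NA-with-warning as documented per function.

## What the generator does and does not emulate

The simulated observer reproduces the generative *structure* assumed for
human estimates — power-law means, constant CV, condition gain, integer
responses — so tests against it validate the analysis chain and the
stimulus/model computations, not human behaviour. It does not model
eccentricity-dependent sensitivity loss, crowding at high densities,
subject exclusion, or sequential effects across trials; empirical
effect sizes from human experiments are therefore outside what passing
tests establish. The stimulus generator likewise does not emulate gamma
correction, display calibration in cd/m², or presentation-software timing;
luminance codes are abstract 8-bit levels (black 0, gray 128, white 255).

## Known limitations

* The exact functional form of density-adaptive influence-sphere shrinkage
  is not established; quantitative fits of the normalized occupancy variant
  depend on the chosen radius law.
* `filter_occupancy` clips dilations at the screen edge (as a physical
  filter would); comparisons with the unclipped geometric union are exact
  only for layouts whose dilated footprints stay on screen.
* The raster union-area routine is O(items × raster cells); it is meant for
  the tens-of-items regime of these displays, not for thousands of points.
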