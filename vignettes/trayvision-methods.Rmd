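---
title: "Methods: segmentation, stereo height mapping and allometric growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, stereo height mapping and allometric growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trayvision)
```

`trayvision` measures early seedling growth in mini-plug trays from
top-view stereo RGB pairs: percentage greenness as a projected-leaf-area
proxy, per-pixel plant height from disparity, and allometric models
linking those optical traits to biomass over time. This vignette records
the methods, the tunable parameters, and the design decisions — including
the places where the problem was genuinely open and the package had to
choose.

## Plant segmentation in HSV space

Foliage occupies a compact region of HSV color space while peat, tray
plastic and specular highlights do not, so classification is a box test in
cylindrical coordinates: a pixel is *plant* when its hue lies on a
configurable arc and its saturation and value fall inside configurable
bands. Conventions (`hsv_segment()`):

* hue in degrees `[0, 360)`, saturation and value in `[0, 1]`; achromatic
  pixels (S = 0) take hue 0 by convention, so they are selectable only when
  `sat_min = 0`;
* all six bounds are inclusive on both ends;
* `hue_min > hue_max` is legal and means the arc wraps through 0° — needed
  for species whose young leaves are reddish-green to red-brown rather
  than green.

The default segment — hue `[60°, 180°]`, saturation `[0.15, 1]`, value
`[0.15, 1]` — is a deliberately generous green arc that excludes dark soil
(low V), gray highlights (low S) and the orange-brown peat hues. It is an
engineering default, not a universal constant: the selection is sensitive
to the light source, which is why every bound is overridable per camera
through the INI `[hsv]` section.

Products are the *green-only* image (non-plant pixels replaced by bit-exact
black, which is also what the stereo matcher consumes) and greenness,
`100 · n_plant / n_total`, over the whole frame or a rectangular ROI
(0-based, half-open, origin top-left — per-half-tray readings are a crop,
not a resample). Segmenting a green-only image with the same segment
reproduces the mask exactly: plant pixels are untouched and black fails
any positive `val_min`.

## Stereo height mapping

The rig is a fronto-parallel pinhole pair: two identical cameras
(5 mm lens, 6.79 × 5.43 mm sensor at 1280 × 1024 px) separated by a ≈55 mm
baseline, looking straight down at the tray from `cam_height_mm`. Images
are assumed rectified; no calibration is performed by the package, and
`cam_height_mm` must always be supplied — it is a bench setup quantity
with no sensible default.

Matching (`compute_disparity()`), restricted to mask-true pixels of the
left image:

* **cost**: zero-mean normalized cross-correlation over square windows
  (default 9×9). ZNCC is invariant to local gain and offset, which is what
  residual exposure/gain differences between two "identical" cameras look
  like.
* **search**: integer disparities `[4, 256]` px by default; ties resolve
  to the smallest disparity (the farthest surface), deterministically.
* **subpixel**: parabola through the scores at the winner ±1. This is not
  a luxury: with the reference rig at 500 mm the depth quantum of one
  integer disparity is `ΔZ ≈ Z²/(f_px·B) ≈ 4.8 mm`, so integer matching
  alone could never resolve millimetre growth increments; a quarter-pixel
  disparity error corresponds to ≈1.2 mm of height.
* **validity**: a pixel is rejected when its window is textureless, its
  peak correlation falls below `min_corr` (default 0.5), or the winner
  sits on the boundary of the (clipped) search range.
* **left-right consistency** (default on): the matching is repeated with
  the camera roles swapped and a left pixel survives only if the right
  view matches back to within `lr_tol` (default 1 px). This is the
  standard occlusion/mismatch filter: in the half-occluded strip beside a
  plant the one-way matcher has no correct answer available and will
  confidently report a wrong one; one-way confidence thresholds cannot
  detect that, mutual consistency can.

Heights follow from triangulation, `Z = f_px·B/d`,
`h = cam_height − Z`; non-positive disparities mark occlusion or mismatch
and invalidate the pixel (never an exception), as do heights below a small
tolerance under the tray plane (default 5 mm) or above the camera. Height
maps serialize to 16-bit grayscale PNG storing `round(h·10)+1` (0.1 mm
quantization, 0 reserved for invalid, so 0 mm is distinguishable from
absent); the writer refuses values outside the encodable
`[−0.05, 6553.4]` mm and the reader inverts the encoding bit-exactly.

The scene-level statistic (`summarize_height()`) is the 95th percentile of
valid plant-pixel heights. What "plant height from a height map" should be
is genuinely open — a maximum matches the manual base-to-highest-leaf
measurement but is hostage to single-pixel outliers; a mean under-reports
any canopy with visible lower leaves. The 95th percentile is this
package's definition: close to the maximum, robust to matching outliers.
Mean, median and the count travel alongside so users can pick otherwise.

## Allometric growth models

Biomass accumulation in early seedlings follows a power law in time, and
allometric theory says a trait growing allometrically with biomass follows
the same curve family; the package therefore fits

* power: `y = a·x^b`, by ordinary least squares of `ln y` on `ln x` — the
  standard allometric procedure. It makes noise-free round trips exact and
  corresponds to multiplicative (lognormal) error, which is how biological
  size variables typically scatter. The alternative — direct nonlinear
  least squares — weighs large observations more; it is kept in the test
  suite as an independent oracle, and the two agree within the nonlinear
  fit's confidence interval on noisy data.
* logarithmic: `y = a·ln(x) + b`, by OLS on `(ln x, y)` — the published
  form for greenness-based prediction in broad-leaved species once
  coverage saturates. A constant response gives slope 0, intercept
  `mean(y)`, and an undefined R² (reported `NA`).

R² is reported on the fitting (transformed) scale in both cases.

**Composition.** `biomass = f(trait)` over `trait = g(time)` gives the
growth model directly. Power over power has the closed form
`(a₁c^{b₁}, b₁d)`, reported with R² absent (it is an algebraic identity,
not a fit). Power over log has no closed form in either family; the
composition is sampled on a grid spanning the inner model's fitted range
(100 points by default) and refit as a power law — the family the theory
expects for a biomass-vs-time curve. Both the closed-form and the refit
path are provided; which one produced any published "predicted" equation
is not decidable from the outside, so the package claims neither.

**Evaluation.** Relative metrics normalized by the observed mean:
`RMSE% = 100·√mean((ŷ−y)²)/mean(y)`, `BIAS% = 100·mean(ŷ−y)/mean(y)`.
Mean-normalization was chosen over range-normalization because it makes
both metrics invariant to rescaling the variable (grams vs milligrams);
published percentages computed under another convention are not directly
comparable, which is worth keeping in mind when eyeballing figures from
the literature. Evaluation never extrapolates: predictors are restricted
to the observed range. `RMSE% ≥ |BIAS%|` always (Jensen).

The reference equation table (`reference_growth_models()`) carries the ten
published biomass equations (four species × measured/greenness/height
sources) with each species' sampling days; they drive the round-trip tests
and give `simulate_series()` realistic generating processes.

## The synthetic scene generator

`render_scene()` produces ground-truthed stereo pairs so the whole chain
is testable without hardware. What it emulates:

* a textured soil plane (per-pixel HSV draws from hue 20–40°, S 0.3–0.6,
  V 0.2–0.5 — warm peat tones outside the default plant segment) at
  height 0;
* foliage blobs — ellipses or needle clusters — at fixed heights, colored
  by per-pixel HSV draws inside ranges that sit *strictly inside* the
  plant segment with margins (hue 75–160°, S 0.35–0.9, V 0.3–0.8 before
  jitter), so that segmentation of the rendered 8-bit image reproduces the
  ground-truth mask exactly even after quantization; the spec constructor
  validates these margins rather than trusting them;
* ±10 % multiplicative value jitter per foliage pixel. This is required,
  not cosmetic: flat color would make window correlation degenerate
  everywhere;
* the right view as a true geometric reprojection: every layer shifts left
  by its pinhole disparity `f_px·B/(cam_height − h)`, fractional shifts
  resolved by linear interpolation, nearer layers overwriting farther
  ones.

Truth fields come from the geometry, not from re-analysis: mask, per-pixel
heights, exact greenness, per-layer disparities, an occlusion flag (the
pixel's counterpart in the right view is hidden or off-canvas) and a
*discontinuity band* — pixels within `edge_guard_px` (default 5) of a
height step between two overlapping plants. In that band a window
straddles two disparities over statistically identical texture, so the
scene genuinely contains no information to disambiguate; stereo accuracy
benchmarks conventionally score discontinuity regions separately, and
`height_rms_error()` excludes both flagged sets. Plant-soil borders are
*not* excluded: against a black background the silhouette itself anchors
the correlation at the correct disparity.

What the generator does **not** emulate — and hence what passing tests do
not certify about real trays: leaf curvature and slant within a blob
(every plant is fronto-parallel), overlapping translucent foliage,
specular highlights, illumination gradients, chromatic differences between
the two cameras, rectification error, and circadian leaf movement between
captures. The end-to-end 1 mm figure is a statement about the algorithm on
geometrically faithful input, not about any particular bench.

`simulate_series()` draws `predict(model, t)·exp(ε)`, `ε ~ N(0, σ²)` —
multiplicative lognormal noise, matching the log-scale fitting model —
with `σ = 0` giving exact curve values for round-trip tests.

## Numerical and degenerate-input choices

* Ties in the correlation scan break toward the smallest disparity;
  scanning order is fixed, so results are reproducible to the bit for a
  given seed and configuration.
* Windows with near-zero variance (`≤ 1e-12` after centering) are
  textureless and invalid rather than divided through.
* The subpixel parabola is only evaluated when its curvature is negative;
  the offset is clamped to ±0.5 px.
* An empty height field summarizes to `NA` statistics with a warning, not
  an error; a zero observed mean makes relative metrics undefined and is
  an error.
* RNG discipline: every stochastic routine takes an explicit seed, uses a
  private stream and restores the caller's RNG state, so identical seeds
  give bit-identical scenes and series regardless of surrounding code.

## Problem sizes used by the shipped tests

Unit and property tests run on small canvases (roughly 80–420 px a side,
2–5 plants) where matching takes a second or two; the end-to-end
height-resolution check and the acceptance script render one full
1280 × 1024 scene with 20 elliptical plants at 10–100 mm — radii 18–42 px,
i.e. 2–8 cm canopies at the ≈1 mm/px ground sampling of the reference rig
at 500 mm — and run the complete two-pass matching, which takes on the
order of half a minute on one CPU. Growth-model fits are at the published
four-point sampling designs plus randomized round-trip batteries.

## Known limitations

* Rectification is assumed, never performed; real rigs need external
  calibration before `trayvision` applies.
* Block matching measures the *visible canopy surface*; for needle-leaved
  species with sparse canopies the 95th-percentile height of matched
  pixels can differ from a stick measurement to the highest leaf tip,
  whose needle may be thinner than a matching window.
* The greenness statistic saturates once foliage covers the tray —
  composition with a height-based model is the intended remedy, mirroring
  how the two traits complement each other across leaf habits.
* `[camera]` INI settings (exposure, gains, pixel clock) are parsed for
  compatibility with per-camera setup files but deliberately not acted
  upon: the package starts at the saved image.
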