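---
title: "Methods: image-based biomass estimation for benthic flatfish"
author: "soleVision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based biomass estimation for benthic flatfish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soleVision)
```

# The measurement problem

Weighing cultured sole requires netting and anaesthesia; the handling
itself depresses growth, which is exactly the quantity a production
facility wants to track. A camera above the tank plus one object of known
physical size in the scene turns the problem into image analysis: segment
every fish, convert pixels to centimetres through the reference object, and
map body dimensions to weight through the species' allometry. This
vignette describes the models and the numerical choices behind each phase,
what the synthetic data generator does and does not emulate, and the known
limitations.

# Phase 1: size normalization

`resizeToPolicy()` rescales the image, preserving aspect to within one
pixel of rounding, so that the *shorter* side is exactly 1024 px (both
sides are then at least 1024 px). Images already at the target pass
through untouched; smaller images are upscaled bilinearly. The scalar
factor is returned for traceability, but all downstream geometry is
computed on the resized image — the calibration is computed on the same
image, so measurements are scale-correct without undoing the resize.

# Phase 2: segmentation and shape classification

The default backend is classical, chosen so the whole pipeline is
reproducible without a trained detector or annotated photographs:

* background level = image median (the tank floor dominates the image);
* foreground = absolute deviation from the background, thresholded by
  Otsu's method (256 levels) — using the *deviation* image lets one
  threshold catch both dark fish and the white reference;
* a closing with a 3-px disc brush followed by hole filling; low-contrast
  fish sit only a few noise standard deviations above the threshold and
  otherwise lose scattered interior pixels;
* connected components, discarding blobs under `minObjectAreaPx`
  (default 50 px).

Each blob is classified by two scores: circularity 4πA/P² (P from the
convex hull of the pixel centres, plus π for the half-pixel footprint) and
elongation (major/minor extent of the minimum-area rotated rectangle). At
most one blob becomes the reference — circularity ≥ 0.85, ties broken by
maximum circularity then maximum area; blobs with elongation ≥ 1.8 become
fish; anything matching neither rule is dropped with a warning. Masks
touching the image border are flagged `partial` (a truncated silhouette
cannot yield a valid length, so such fish are counted but never measured).
Fish blobs beyond the configured single-fish bounds (elongation > 6 or a
configurable area cap) are flagged `merged`: overlapping fish are reported
as an honest failure rather than measured as one animal. A learned
detector can replace all of this behind the `DetectorConfig`
plugin contract (`image -> list of Detection`).

Detection quality is scored by `matchDetections()`: greedy one-to-one mask
IoU matching per class, reporting per-object recall as "accuracy" — the
documented assumption, since per-object and per-image conventions differ.

# Phase 3: self-calibration and morphometry

The reference is a white 3-D printed hemisphere, diameter 4.2680 cm, which
is a circle from above regardless of orientation. Its pixel diameter is
estimated as the equivalent-area diameter 2√(A/π) — robust to single-pixel
boundary noise, unlike a bounding-box width, which is nevertheless logged
as a diagnostic. The scale is then cm-diameter / px-diameter, and the
identity `scale × diameter_px = 4.2680` is enforced by the class validity.
Masks with circularity below 0.85 raise a typed calibration failure: a
pipeline without a usable reference aborts with an actionable message
rather than guessing a scale. A single isotropic scale is assumed
(top-down camera, flat tank bottom, fish lying on it); no lens-distortion
or water-refraction correction is applied.

Fish dimensions come from the minimum-area rotated rectangle of the mask
(rotating calipers over the convex hull), not an axis-aligned box, which
would overestimate length by up to √2 at 45°. Two numerical details
matter:

* **Near-tie resolution.** Pixelation perturbs hull edges enough that the
  strict area minimizer can tilt a degree off a symmetric body's axis,
  padding the minor extent; among rectangles within 0.5% of the minimal
  area the most elongated is used.
* **Extent correction.** Pixel-centre calipers underestimate the true
  support of a smooth convex boundary. Near a support point with curvature
  radius R, the expected depth of the first grid point is
  d\* = (1.5/√(8R))^(2/3), capped at the half-pixel value that applies when
  the tangent is grid-aligned; each extent is corrected by 2d\*, with R
  estimated from the rectangle itself as for an ellipse (a²/b at the side,
  b²/a at the tip). A flat +1 px correction — the usual convention — left a
  systematic ≈ +0.6% width bias at the benchmark's 60–200 px body widths.

With this estimator, median relative errors on the synthetic benchmark
(200 fish, 20–40 cm, ≥ 200 px long) are ≈ 0.1% for both length and width,
measured by the acceptance script each run.

# Phase 4: the dimensions-to-weight regressor

Weight prediction uses a nine-layer fully connected network. "Nine layers"
counts the widths 2–64–64–32–32–16–16–8–1 (input, seven hidden ReLU
layers, linear output); with two scalar inputs, convolutions would be
meaningless, so a dense architecture is the well-posed reading of a
nine-layer regressor on (height, width). The optimizer is adam with
learning rate 0.001 and mini-batches of four records; the loss is
mean-squared error. Inputs and target are log-transformed and then
standardized on the training split. Allometric growth W = α·L^β·w^γ is
*linear* in log space, so the network only has to learn a near-linear map:
this keeps it accurate at the sparse corners of the training range, where
a raw-scale network disagreed with the closed-form baseline by several
percent. Epochs (2000 max), early-stopping patience (100 epochs on the
mean training loss) and the 80/20 train/test split are configurable
defaults; training is bit-reproducible from its seed, which drives the
split, the He initialization and the batch order.

The closed-form baseline — OLS of log W on log L and log w — is fitted on
the same training split and stored in every model. It is the oracle in
tests (on noise-free power-law data it recovers the generating
coefficients to machine precision, and the network must agree with it
within 1% across the training range), the fallback regressor
(`allometricBiomassModel()`), and the source of ground-truth weights in
the synthetic scenes.

Fit quality is reported as R² = 1 − SS_res/SS_tot on the gram scale, with
the conventions R² = 1 for a perfect fit of a constant target and R² = 0
when SS_tot = 0 with nonzero residuals. On the noise-free 400-record
table the held-out R² exceeds 0.9997 (recomputed by the acceptance
script). Models serialize to versioned JSON at 17 significant digits, so a
save/load round trip predicts bit-identically.

# Growth statistics

Before/after cohort analysis uses Student's paired t test within each
group (t = mean(d)/(sd(d)/√n), df = n−1) and compares per-fish increments
between groups with a two-sample test. The between-group test family is
not fully determined by the reporting conventions it mirrors; Welch's
variant is the default (it equals the pooled test exactly when group sizes
and variances coincide, and is safer otherwise), with the pooled variant
selectable. Two-sided p values come from the incomplete-beta relation
P(|T| ≥ t) = I_{df/(df+t²)}(df/2, ½), evaluated with `pbeta`; tests pin
agreement with the reference t CDF to 1e−8 and empirical type-I error at
α = 0.05 to [0.03, 0.07] over 1000 null simulations. Summaries follow the
mean ± SEM convention (SEM = sd/√n, undefined at n = 1) plus the gainer
percentage — the share of fish with a positive increment, rounded to two
decimals. No multiple-testing correction is applied, matching the
single-comparison design it serves. Increments are reported in kg (and
interpretable as percentages of initial weight); the package deliberately
reports both rather than adopting any single increment unit.

# The synthetic generators

`renderScene()` emulates what drives the measurement pipeline — shape and
contrast — and nothing else: a uniform grey tank floor (intensity 0.45),
sole silhouettes as tapered ellipses (an ellipse whose tail half-width is
scaled by 1 − taper·u², keeping total length and maximum width exact),
one white circle at the true metric scale, and additive Gaussian pixel
noise (sd 0.02) applied *after* the exact masks are recorded. Default
study conditions: 1024² px scenes at 0.1 cm/px, five fish of 20–40 cm
with width/length ratios 0.30–0.50, fish grey levels 0.15–0.30, placed by
rejection with a 6 px clearance margin. Everything is a pure function of
(parameters, seed).

What the renderer does **not** emulate — and therefore what passing
benchmarks do not demonstrate on real photographs: skin texture and
camouflage against the tank floor, partial burial in sediment, water-column
refraction and surface glare, uneven illumination, occlusion and true fish
overlap, and lens distortion. The classical detector is expected to be the
first casualty of those effects; the plugin contract exists so a learned
detector can take its place while calibration, morphometry and weight
prediction carry over unchanged.

`generateBiomassDataset()` draws lengths uniformly (20–40 cm), widths as
length × uniform aspect (0.30–0.50), and weights from
W = α·L^β·w^γ·e^ε with ε ~ N(0, log(1+cv)). Defaults β = 2, γ = 1, and α
calibrated so a 35 × 14 cm sole weighs 750 g — plausible flatfish scaling
around the adult sizes of interest; the parameter-recovery tests are
agnostic to these values. `generateGrowthCohort()` builds two 15-fish
groups over three replicate tanks sharing one initial-weight distribution
(0.75 ± 0.35 kg), with final weight = initial × (1 + effect + noise).
Default effects are 2.5% (control) and 11% (experimental) with relative
noise sd 0.05; the noise default was fixed by a Monte-Carlo power check
over 1000 seeds (the paired test detects the 11% effect in ≥ 95% of
cohorts) before any test depended on it.

The tank floor area needed for stocking density is not derivable from a
tank's volume alone, so density is only reported when the area is given
explicitly in `PipelineConfig`; the worked default of 2.25 m² is
reverse-engineered from five ≈ 0.75 kg fish at ≈ 1.67 kg/m².

# Degenerate inputs and tie-breaks

* Overlapping or out-of-frame objects: scene rendering rejects them unless
  overlap is explicitly allowed.
* Several circular blobs: one reference survives (max circularity, then
  max area); the rest are re-tested against the fish rule or dropped.
* Sub-minimal masks (< 20 px): typed `degenerateMask` error rather than a
  garbage measurement.
* Constant-weight training tables: the standardization guard keeps sd > 0,
  the network learns the constant, and the R² conventions above apply.
* Rank-deficient allometric designs (no independent variation in
  dimensions): typed degenerate-fit error.
* Fish numbering: sorted by bounding-box top-left (row, then column) —
  deterministic ids without any tracking across images.

# Problem sizes

The shipped benchmarks use 50 scenes × 5 fish for detection, 40 scenes
(200 fish) for measurement error, one 400-record noise-free table for the
regressor, 20 tanks for the end-to-end biomass check, and 1000-replicate
simulations for the statistical calibrations; together they run in a few
minutes on one CPU. All sizes are parameters of the corresponding
functions and scale up directly.

# Known limitations

* The classical detector is tuned to high-contrast synthetic scenes; on
  real imagery it is a starting point, not a result.
* No uncertainty is attached to per-fish weights beyond the regressor's
  held-out RMSE.
* The planarity assumption (single isotropic scale) ignores perspective
  and refraction; a camera model would be needed for deep tanks or
  off-centre references.
* Merged (overlapping) fish are flagged, not separated; densely stocked
  tanks will under-report measurable fish.
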