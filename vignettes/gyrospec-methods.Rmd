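---
title: "gyrospec: models, design choices and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gyrospec: models, design choices and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gyrospec)
```

`gyrospec` is a desk-scale reconstruction of an invasive-plant
detection system built around a pushbroom imaging spectrometer flown
on an ultralight gyrocopter. No real imagery ships with the package;
every input is synthesized by code under explicit statistical
assumptions. This vignette records those assumptions, the parameters
that matter, the genuinely open design decisions and how they were
resolved, and — importantly — what a passing test suite does and does
not establish.

## 1. The scene model

The world is a fine rectangular grid (default cell `g_fine` = 0.05 m)
carrying three aligned layers: a digital terrain model, a crisp
per-cell class label, and a per-cell patch id. The fine cell is the
atom of ground truth: at 0.05 m, a 0.5 m analysis pixel contains
exactly 100 cells, so 50% coverage — the detection threshold of
0.125 m² per 0.25 m² pixel — is representable without discretization
ambiguity, and coverage aggregation is exact (the area-conservation
test asserts equality, not approximate equality).

The target species grows in two forms seen in real clonal succulents:
dense discs (default 16 discs of radius 1–4 m; clonal mats are
typically meters across) and thin "tendrils" — wandering polylines
0.2 m wide that cross pixels without ever filling one. Background
vegetation tiles the rest in 5 m blocks, four classes: two sclerophyll
shrubs, a conifer whose stressed form is withered needles over litter,
and a succulent halophyte. Every disc, tendril and block is a *patch*
with its own vigour `condition` drawn uniformly on [0, 1].

Terrain relief (`flat`, `ramp`, `smooth_random`, amplitude 5 m by
default) exists to exercise the ray–DTM machinery; the scenes are
coastal lowland, not mountains, and occlusion/foldover on steep
terrain is explicitly out of scope.

## 2. The spectral model and its calibration

Each class has two 200-band endmembers, *vigorous* and *stressed*,
built from a phenomenological vegetation-reflectance generator (green
peak, red absorption, logistic red edge, NIR plateau, 970 nm water
feature). A patch at condition *c* has mean spectrum
`(1 − c)·vigorous + c·stressed`. Variability then has two scales:

- a **patch-level** band-correlated offset (σ = 0.003, Gaussian,
  correlation length 10 bands), shifting a whole patch coherently;
- a **pixel-level** band-correlated term (σ = 0.006) added during
  acquisition, modeling the tonal heterogeneity visible inside real
  patches (dead areas, intermediate tonalities).

The quantitative variances are free parameters (no source states
them). They were calibrated once, against the *described behaviour* of
the real system rather than its scores: pure pixels of different
classes are reliably discriminated, and errors concentrate in
sub-pixel mixtures and in the reddish halophyte. Two earlier variants
failed that description — endmembers so similar that pure
target/halophyte pixels were statistically inseparable, and a
patch-constant perturbation that produced *whole-patch* blocks of
correlated false positives, an error structure the real protocol
never exhibits. The shipped library keeps the
halophyte as the target's nearest neighbour in spectral-angle terms
(0.098 rad to the stressed target, well below the target's own
vigorous-to-stressed angle of 0.198 rad — the "similar between classes,
variable within class" regime) while giving it a consistently deeper
970 nm water feature as the systematic discriminant. This is the main
reason a green end-to-end test should be read modestly: the simulated
classes are separable *by construction*; the test establishes that the
pipeline loses little of that separability, not that any real species
pair is separable.

## 3. Flight, sensors and the AHRS

The trajectory is a straight north-flown line at constant speed
(default 65 km/h = 18.06 m/s) and height (300 m). Attitude wander is
an independent stationary AR(1) per axis (σ = 1°, lag-1 ρ = 0.95 at
the 36 Hz line rate), the simplest process with the right marginal
spread and correlation time (~0.5 s) for a low-inertia rotorcraft.
Positions stay exactly on the nominal line; translating turbulence is
not modeled, so the constant-velocity assumption in the filter is
exact rather than approximate — a stated simplification.

Sensors: GPS = truth + white noise (σ = 2 m, 20 Hz); gyros = true
Euler rates + random-walk bias (σ_b = 1e-4 rad/s/√s) + white noise
(σ = 0.005 rad/s) at 100 Hz; an absolute attitude reference
(gravity-derived roll/pitch, course-derived heading; vertical-gyro
grade, σ = 0.1° at 10 Hz). Without that reference, yaw — and the yaw
gyro bias — is unobservable; the filter then only dead-reckons
attitude. The IMU sampling grid is augmented with the line timestamps
so that noise-free strapdown integration reconstructs the
piecewise-linear attitude truth exactly; this is what makes the
zero-noise degenerate test an equality test.

Fusion is a 12-state (position, velocity, attitude, gyro bias) linear
Kalman filter, followed by a Rauch–Tung–Striebel smoother:
geocorrection is post-flight batch processing, so the per-line pose may
legitimately use future measurements. Two numbers drove the design:
0.5 m at 300 m is 0.095°, so the attitude solution must be good to a
few hundredths of a degree, and with σ_gps = 2 m the position error
over one 28 s line is information-limited to the straight-line
regression error of its GPS fixes (~0.1–0.2 m typical, with occasional
~0.4 m constant offsets — a single flight line can simply draw an
unlucky GPS bias, which is why the geolocation acceptance bound is
evaluated over pooled replicate flights, and why ground control points
exist). Process noise defaults: σ_accel = 0.02 m/s²·√s (nominally
constant-velocity platform), attitude/bias process noise from the gyro
spec. Filter health is regression-tested via the normalized innovation
squared (mean ≈ 3 for the 3-dof GPS updates).

## 4. The imaging model

Body axes are x forward, y right, z down; the body-to-map rotation is
`Rz(yaw)·Ry(pitch)·Rx(roll)` (stated explicitly because nothing fixes
the convention). Detector *d* of *D* looks `FOV·((d−1)/(D−1) − ½)`
across track, so the extreme detector centers span exactly
`2h·tan(FOV/2)` — 220 m at 300 m with the full-system default
`FOV = 2·atan(110/300)`. The default detector count (640) puts the
ground sampling (0.34 m across × 0.5 m along) in the claimed 5–8
pixels/m² regime; desk-scale configurations narrow the swath but keep
the same resolution law.

Each (line, detector) footprint — across-track IFOV × along-track
`v·t_int` — is point-sampled on the fine grid at `g_fine` spacing.
Because the fine class map is crisp, point sampling makes the mixing
weights *exactly* the sampled area fractions: weights sum to one by
construction and the mixing test asserts exact convex combinations.
There is no PSF convolution; footprint-edge mixing is the only mixing.
Sensor noise is additive i.i.d. Gaussian per band with
σ = mean(signal)/SNR, default SNR = 100; no shot noise, smile,
keystone or detector nonuniformity. A footprint that leaves the scene
makes that pixel nodata rather than aborting the line.

## 5. Geocorrection

Each cube pixel is projected through its line of sight onto the
bilinearly interpolated DTM. The scalar reference implementation
(`intersect_dtm`) marches the ray at `g_fine` steps and bisects to
1e-3 m; the cube-scale path (`project_rays`) uses a fixed-point
iteration on the slant range, and a property test pins it to the
scalar oracle. Intersections outside the DTM extent are nodata, never
extrapolated.

The ortho grid is filled by *gathering*: each output cell takes the
spectrum of the nearest projected pixel within one pixel radius, else
nodata. Nearest-neighbor (not bilinear) resampling keeps spectra
bit-identical through geocorrection — asserted with `expect_identical`
— which matters because the classifier consumes them. Gathering avoids
the holes a forward scatter would leave.

GCP residual correction fits a least-squares affine (≥3 points) or
second-order polynomial (≥6) warp from GCP pairs and resamples the
ortho grid under the inverse mapping (fitted on the swapped pairs).
It operates on the ortho grid, not on pre-rasterization pixel
positions — the simpler and directly testable of the two readings, at
the cost of one extra resampling step. Least squares over a family
containing the identity guarantees the GCP RMS never increases. In
the default synthetic pipeline there is no boresight/calibration error
to correct, so the stage runs only when GCPs are supplied.

## 6. Classification

All 200 bands feed an RBF-kernel C-SVC; there is deliberately no band
reduction anywhere on the path from cube to classifier. Because no SVM
library is available in the deployment environment, the dual problem is
solved in-package by SMO with maximal-violating-pair working-set
selection; perfect separation of separable classes and determinism
(identical inputs → decision values equal to 1e-9) are under test.
Multiclass is
one-vs-rest with post-hoc collapse to target/others; on separable toy
data this provably coincides with a directly trained binary machine
(consistency test).

Hyperparameters: C and γ by stratified 5-fold cross-validated grid
search (C ∈ {1, 10, 100}; γ = median heuristic × {¼, 1, 4} — the
1/n_bands convention is far too flat for reflectance vectors whose
pairwise distances are ≪ 1). Features are raw reflectances; a
standardization flag exists but defaults off.

Training emulates on-image ground truthing: per class, `n_per_class`
(default 80) pixels from a labeling window, labeled by the
detection-threshold rule. For the target, 30% are *mixed* pixels
(coverage between threshold and full pixel); for background classes
the same fraction is drawn, where available, from sub-threshold target
fringes (0 < coverage < threshold). Labeling whole areas on the image
naturally includes both kinds of boundary pixel, and both matter: the
first teaches the classifier to find sub-pixel patches, the second
teaches it where presence *stops* — without the hard negatives the
target boundary is unconstrained from below and commission error on
patch fringes rises sharply.

## 7. Validation and reporting

Reference truth is the thresholded coverage map (boundary inclusive:
exactly 0.125 m² counts as presence). Validation samples 100 pixels
classified as target and 250 classified as other, uniformly without
replacement over the whole image, excluding training pixels; the
error matrix rows are classification, columns reference. Accuracies
are reported in percent, rounded half-up to one decimal from unrounded
intermediates (base `round()`'s half-even rule does not reproduce
published tables); kappa is reported truncated at three decimals,
the convention that reproduces all published reference values this
package uses as golden tests, with the unrounded value retained
alongside. Degenerate ratios (empty row/column, p_e = 1) are reported
as undefined, never as zero.

One subtlety: with strata of 100 + 250 on an image whose background
dwarfs its target, user's accuracy is brutally sensitive — a 1%
background-to-target leak contributes tens of false positives to a
~400-pixel classified-target population. This is faithful to the
protocol, and it is why the end-to-end acceptance bound is on overall
accuracy.

## 8. Pipeline, seeds and formats

`run_pipeline()` composes the stages; every stochastic stage receives
`derive_seed(master, stage_name)` — a stable string hash, so adding a
stage never reshuffles the others. Artifacts: ASCII grids (terrain,
class and classified maps), ENVI BIL cube and BSQ orthoimage with
wavelength and map-info headers, CSV poses/labels/library, JSON report
and a manifest with per-file seeds and MD5 checksums. Re-running a
config byte-reproduces the report (under test). Configuration is JSON
(no YAML parser in the deployment environment) with unknown-key
rejection. GeoTIFF interchange was dropped for the same environmental
reason: ENVI + ASCII grid are the raster interfaces.

## 9. Known limitations

- No radiative transfer, BRDF, atmosphere or illumination geometry;
  "reflectance" is generated directly.
- Small-angle linearized attitude throughout (no quaternion
  mechanization); fine for ≤ a few degrees of wander, wrong for
  aerobatics.
- Positions never leave the nominal track, so the filter's
  constant-velocity model is exact; real turbulence would degrade the
  position solution toward the GPS-regression floor discussed above.
- Synthetic class separability is by construction (Section 2); a green
  suite validates the pipeline, not botany.
- Single flight line per run; no multi-strip mosaicking.
- The error-matrix module is 2×2 (target vs others); no area-weighted
  estimators, kappa variances or between-matrix significance tests.
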