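---
title: "Methods: NIR hyperspectral chemometrics with hsichem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR hyperspectral chemometrics with hsichem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hsichem` implements a complete chemometric pipeline for two-class variety
identification from near-infrared hyperspectral cubes, together with a
synthetic-scene generator that makes every stage testable without
instrument data. This vignette explains the models and procedures, the
parameters that matter, and the design decisions taken where the
methodology is genuinely open.

## The measurement model and reflectance correction

A line-scan NIR imaging system records raw counts that confound the scene
reflectance with illumination and dark current. With a white reference
frame $I_w$ (a high-reflectance standard) and a dark frame $I_d$ (shutter
closed), the relative reflectance is

$$I_c = \frac{I_r - I_d}{I_w - I_d},$$

applied elementwise with 2-D reference frames broadcast across bands.
`correct_reflectance()` refuses frames where white does not exceed dark
everywhere, since the ratio is then undefined. Reference frames may be
full-frame rasters or per-band 3-D arrays.

## Segmentation and object labeling

Foreground objects are much brighter than the dark background in the
short-NIR, so a single-band threshold suffices: the band nearest 1119 nm
(ties in the nearest-band lookup resolve to the lower wavelength) is
binarized at reflectance 0.122. The comparison is strict (`>`): a pixel
exactly at the threshold counts as background, a deliberately conservative
foreground rule. Connected components are formed under 8-connectivity and
components smaller than 5 pixels are discarded as salt noise; both choices
are conventional for granular-object imagery where kernels may touch
diagonally across a single pixel and sensor noise can flip isolated
background pixels above threshold.

## Spectral preprocessing

Pixel spectra are preprocessed in the order *wavelet smoothing, then SNV*,
and object-wise spectra are computed *after* preprocessing as the plain
arithmetic mean over each ROI's pixel rows.

**Wavelet smoothing.** Each spectrum is decomposed with the Daubechies-7
filter bank to level 3, using symmetric (half-sample) boundary extension,
and reconstructed from the level-3 approximation with all detail
coefficients set to zero. This rule is deterministic and parameter-free,
and it is linear, which lets the package apply it to large pixel tables as
a single precomputed bands-by-bands matrix product. A soft-threshold
variant (universal threshold from the finest-level MAD) is available via
`wt_smooth(threshold = "soft")` for users who prefer classical
wavelet denoising; it is nonlinear and therefore slower on tables. The
implementation was validated coefficient-by-coefficient against an
independent wavelet library; those frozen reference values live in the
test suite. Three decomposition levels with a 14-tap filter require
spectra of at least a few dozen bands; the 200-band axis is comfortable.

**SNV.** The standard normal variate centers each spectrum to mean zero
and scales it to unit standard deviation. The package uses the *sample*
SD (denominator $n-1$); the choice is a documented constant, and all SNV
postconditions in the tests are stated against it. SNV removes exactly a
per-spectrum affine transform — which is why the scene generator's scatter
model (one multiplicative gain and one additive offset per pixel, shared
across bands) is annihilated by it, and why any grade effect that is a
common rescaling of all absorbance dips is invisible after SNV (see the
drift discussion below).

Zero-variance spectra make SNV undefined; the offending row indices are
reported in the error.

## Effective-wavelength selection

**From PCA loadings.** PCA is fit to the calibration spectra
(column-centered, unscaled). Bands are scored by the maximum absolute
loading across the retained leading PCs. The number of retained PCs
defaults to the smallest number whose cumulative explained variance
reaches 99 %, capped at 7 — the usual retention rule for NIR spectra,
where a handful of components carry essentially all variance. Candidate
bands are restricted to *local maxima* of the score vector (a plateau of
equal scores collapses to its lowest-wavelength band), because absolute
loadings are smooth in wavelength and unrestricted top-$k$ ranking would
select runs of adjacent, redundant bands. The top `n_select` peaks are
taken, ties resolving to the lower wavelength; if there are fewer peaks
than requested, the highest-scoring non-peak bands fill the remainder.
Defaults of 20 (object-wise) and 17 (pixel-wise) wavelengths mirror common
practice of keeping roughly a tenth of the axis; both are plain
parameters.

**From ICA weights.** FastICA (fixed-point iteration, logcosh contrast,
symmetric decorrelation) is fit on centered, SVD-whitened data with a
seeded random orthogonal start; the unmixing matrix `W` acts on centered
data, `S = X_c W^T`. Bands are scored by the mean absolute unmixing weight
across components and the top `n_select` are kept. Components default to 7,
mirroring the PCA retention cap. ICA is defined only up to permutation and
sign, which the tests acknowledge by matching sources through maximal
absolute correlation; non-convergence after `max_iter` iterations is an
error, not a silent result.

## Classifiers

* **SVM** (RBF kernel, via `e1071`): `C` and `γ` are grid-searched over
  `2^-8 … 2^8` — integer log2 steps by default, configurable finer — by
  stratified $k$-fold cross-validated accuracy (default 5 folds, seeded
  fold assignment). Ties resolve to the smaller `C`, then the smaller `γ`;
  the winner is refit on all calibration rows. The spectra are already
  SNV-normalized, so the SVM's internal rescaling is disabled for
  determinism.
* **k-NN**: Euclidean distance, majority vote (optionally
  inverse-distance weighted). Tie-breaking is fully deterministic: equal
  distances admit the lower training-row index first, and a tied vote
  falls back to the single nearest neighbor's class. This determinism is
  why the package implements prediction itself rather than delegating to
  a library routine with randomized ties.
* **RBF network**: an exact RBF expansion — one Gaussian hidden unit per
  training row with a common `spread` — and a ridge-regularized
  least-squares readout onto one-hot class indicators. With `ridge = 0`
  and distinct rows the network interpolates its training labels exactly;
  `spread → ∞` degenerates toward majority-class prediction. The spread
  can be fixed or tuned by the same CV protocol as the SVM grid.

**Representative-pixel selection.** Pixel-level calibration sets are
enormous (hundreds of thousands of spectra at instrument scale), so the
pixel calibration set is shrunk per variety by k-means into `n_groups`
clusters (k-means++ seeding, 10 restarts, fixed seed, via `stats::kmeans`)
keeping each cluster's nearest-to-centroid row. 3000 groups is the
instrument-scale setting; desk-scale runs default to 300. If there are no
more distinct rows than groups the selection is the identity, and empty
clusters simply yield fewer representatives (the realized count is
reported).

## Evaluation designs

Scenes are split 2:1 into calibration and prediction *at the scene level*
within every class-grade group (`floor(2n/3)` scenes to calibration), so
no pixel of a prediction scene ever influences calibration.

The **four-way design** crosses calibration level and prediction level:
pixel-trained models predict pixel rows directly and predict an object by
scoring the object's average preprocessed spectrum; object-trained models
predict object rows and pixel rows directly. The average-spectrum
mechanism is the natural reading of a design whose calibration metrics
repeat between the two prediction levels of the same model, and that
repetition is asserted in the tests. Calibration metrics are
resubstitution on the training rows.

The **grade-transfer design** trains one model per size grade on *all*
scenes of that grade and predicts every grade, producing a 3×3 grid whose
diagonal is resubstitution. Sensitivity is the per-class accuracy of the
first variety, specificity that of the second; accuracy, in percent, is
the pooled correct fraction. All metrics are recomputed from integer
confusion counts kept in numerator/denominator form.

**Prediction maps** paint per-pixel predicted classes back into the scene
raster (background = NA). The raster is constructed directly from the
tabular predictions, and the tests assert bitwise agreement between the
two. Rendering uses a fixed two-class colormap; scores images are min-max
scaled per image, a display-only choice.

## The synthetic-scene generator

The generator emulates the statistical structure of NIR images of dried
fruit on a dark conveyor:

* **Signatures.** Each class is a reflectance baseline minus Gaussian
  absorbance dips at 1123, 1210, 1308 nm (C–H stretching overtones) and
  1473 nm (water, the deepest default dip), differing between classes in
  baseline and dip depths by a few percent reflectance.
* **Geometry.** Objects are random non-overlapping ellipses (axis ratio
  0.6–1.0) rather than circles, so connected-component labeling is
  exercised non-trivially; mean radius decreases Grade1 > Grade2 > Grade3.
* **Optics.** `raw = dark + (white − dark) · (ρ · gain + offset + noise)`
  clipped to the sensor range [0, 1], with white ≈ 0.9 and dark ≈ 0.02
  plus deterministic spatial ripple, so the white/dark correction is a
  nontrivial normalization and inverts the model exactly when noise and
  scatter are off.
* **Scatter and noise.** One multiplicative gain (SD 0.08) and one
  additive offset (SD 0.01) per pixel, shared across bands — the classic
  scatter structure that SNV removes — plus independent per-pixel-per-band
  sensor noise. The offset SD is kept small enough that background pixels
  at the segmentation band stay below the 0.122 threshold by more than
  four standard deviations.
* **Noise level.** The default `noise_sd = 0.035` was calibrated once so
  the generated studies reproduce the difficulty pattern reported for
  real instrument data of this kind — pixel-wise classification in the
  low-to-mid 90s and object-wise near-perfect, with the object-wise
  advantage arising exactly as it does physically: per-pixel noise
  averages out in ROI means. At this level per-object segmentation
  overlap (Jaccard) stays above 0.95 and object counts remain exact.
* **Grade drift.** `grade_drift` injects a grade-dependent *shape* change:
  the water dip deepens with grade while the C–H dips weaken, in both
  classes (a common covariate shift, as with size-dependent drying). A
  uniform rescaling of all dips was rejected because it is an affine
  spectral change that SNV removes exactly — it provably cannot produce a
  grade effect after preprocessing.
* **Study layout.** 2 classes × 3 grades × `scenes_per_group` scenes, one
  class per scene, per-scene seeds derived deterministically from a master
  seed. The full layout is 30 scenes per group (180 scenes); the desk
  preset uses 6 scenes per group of 64×64 pixels, which keeps a complete
  study analysis within a couple of minutes on one CPU.

What the generator does **not** emulate: real absorbance band shapes and
covariances, within-class chemical heterogeneity, kernel surface texture
and curvature, line-scan motion blur, wavelength-dependent illumination
drift, dead pixels. Passing tests therefore demonstrate that the pipeline
is correct and that it recovers known structure under a realistic noise
model — not that any particular accuracy would be attained on real
instrument data.

## Numerical choices and degenerate inputs

* Wavelet boundary handling is symmetric extension; edge bands are
  consequently smoothed against their mirror image.
* The nearest-band lookup breaks distance ties toward the lower
  wavelength; the segmentation threshold is strict.
* k-means++ restarts pick the lowest within-cluster sum of squares; a
  degenerate set with at most `n_groups` distinct rows bypasses k-means
  and returns first occurrences of the distinct patterns.
* SVM grid ties and spread-grid ties resolve to the smaller parameter;
  k-NN tie rules are described above.
* Classifiers refuse feature-dimension and preprocessing-stage
  mismatches, missing labels, and single-class training sets.
* All randomness flows through explicit seeds (`with_seed` saves and
  restores the caller's RNG state); derived seeds stay below $2^{31}$.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run the desk preset: 64×64×200
cubes, 6 scenes per class-grade group (36 scenes, ≈18,000 object pixels),
300 representative-pixel groups, a 9×9 `(C, γ)` grid, and 48×48 scenes
for the five grade-transfer replicates. These sizes were chosen so a full
study analysis completes in minutes; the `paper` preset of
`run_config()` carries the instrument-scale constants (200×200 scenes,
30 scenes per group, 3000 k-means groups, 17×17 grid).

## Known limitations

Binary classification only (the API keeps multiclass room, but the
evaluation designs assume two varieties). The ENVI reader handles the
BSQ/BIL double-precision dialect the writer emits, not the full format
zoo. FastICA uses the logcosh contrast only. Grade-transfer uses all
scenes of the training grade rather than an inner split, so its diagonal
is resubstitution by construction.
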