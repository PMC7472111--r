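---
title: "Methods: hyperspectral estimation of leaf nitrogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral estimation of leaf nitrogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrospec)
```

`nitrospec` estimates leaf nitrogen content (N%, percent of dry mass) from
proximal hyperspectral reflectance. This vignette documents the methods: the
models, their assumptions, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the package's known limitations.

## From raw sensor data to per-leaf signatures

**Reflectance calibration.** Hyperspectral cameras record intensity, not
reflectance. `calibrate_cube()` applies, per pixel and band,

$$ r = \frac{i_\mathrm{plant} - i_\mathrm{dark}}{i_\mathrm{white} - i_\mathrm{dark}}, $$

where the dark-current frame captures the detector offset and the white
reference the illumination-times-sensitivity product. The division is guarded:
elements where $|i_\mathrm{white} - i_\mathrm{dark}|$ falls below $10^{-9}$
(intensity units) are set to `NA` and reported in an invalid-pixel mask rather
than silently producing infinities. The assumption is a temporally stable
illumination field between reference and plant acquisitions.

**Splice-jump correction.** Full-range spectrometers multiplex several
physical detectors; at each hand-over the signature shows a step
discontinuity. `remove_jumps()` fits a least-squares line through the trailing
`m = 6` points of the segment left of each junction, extrapolates it one band
into the right segment, and shifts the *entire* right segment additively so
its first value lands on the extrapolated line. Junctions are processed left
to right so corrections cascade. The additive form preserves all first
differences within a segment — the spectral *shape* each detector measured is
never distorted, only its level. A multiplicative alignment would instead
preserve ratios; we chose the additive form because the step artefact is an
offset in the detector electronics, not a gain error, and the correction is
then exactly idempotent. `m` is tunable (`jump_params(m = ...)`, minimum 2);
6 points balance noise averaging against curvature bias of the local-linear
model.

**Smoothing and trimming.** Random noise is reduced with a Savitzky–Golay
filter (`smooth_spectrum()`, default window 11 bands, polynomial order 2 —
the classic setting that preserves band shape while averaging ~1 nm noise on
a dense grid; both are exposed). The spectral extremes, where detector
sensitivity collapses, are removed (`trim_spectrum()`, defaults 400 and
2400 nm). The pipeline order is: jump removal, then smoothing, then trimming
— smoothing across an uncorrected step would smear it into neighbouring
bands.

**Leaf-bed detection.** Leaves are bound to a bed with a black background and
a blue fiducial marker. Marker pixels are found by the spectral angle mapper:
`spectral_angle(a, b) = acos(a·b / (‖a‖‖b‖))`, strictly below a 0.2 rad
threshold against a target signature averaged from annotated marker pixels.
The angle is invariant to positive scaling, hence to illumination intensity.
The threshold is in radians — the only dimensionally sensible reading of a
0.2 cut-off for an arccosine output. The bed ROI is placed from the marker's
centroid and principal axis (eigenvector of the pixel-coordinate covariance),
displaced by rig-specific offsets that are configuration, calibrated once per
installation; the defaults match the synthetic scene layout.

**Leaf segmentation.** Within the ROI, pixels are mapped to *hyper-hue* — the
signature minus its mean, normalised to unit length — which removes the
achromatic (brightness) component and intensity scaling, leaving only the
spectral *direction*. The cited hyper-hue construction also defines
saturation and intensity channels; only the hue direction discriminates leaf
from background here, so the other channels are omitted. Exactly constant
(achromatic) pixels have no hue and are mapped to background. A one-class
support vector machine (radial-basis kernel) is trained on hue vectors from
known leaf regions; `nu = 0.1` bounds the fraction of training pixels treated
as outliers, and the kernel bandwidth uses the median heuristic
(`gamma = 1/(2·median²)` of pairwise training distances). Because `nu` also
floors the miss rate, a 3×3 majority vote inside the ROI cleans the
salt-and-pepper misclassifications the margin produces; it flips isolated
pixels only and can be disabled (`clean = FALSE`). Around 300 training pixels
are recommended: with ~50-band hue vectors, much smaller samples leave the
boundary under-determined and held-out recall falls visibly below
`1 - nu`. Masked pixels are averaged per band (`mean_signature()`); an empty
mask raises a typed condition that callers record as an acquisition error.

**VNIR+SWIR merging.** Signatures from separate VNIR and SWIR cameras are
concatenated on one grid with two detector segments and passed through the
same jump correction. The grids must not interleave; when they share the
boundary wavelength the VNIR value is kept and the SWIR duplicate dropped
(the VNIR detector is the better-behaved instrument at its long-wavelength
end). Per-segment FWHM metadata (5.5 nm / 12 nm for the default camera pair)
is preserved.

## Spectral band resampling

A sensor band is modelled as a Gaussian spectral response centred on the band
centre with $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$. The weight of source
band $s$ in destination band $d$ is the destination response evaluated at the
source centre, zeroed when the FWHMs do not overlap, i.e. when
$|\lambda_d - \lambda_s| > (\mathrm{FWHM}_d + \mathrm{FWHM}_s)/2$, and rows
are normalised to sum to one *after* truncation. Sampling the response at
source centres (rather than integrating response products) is standard
practice when the source grid is dense relative to the destination bandwidth,
as with 1 nm spectrometer output. Consequences of the convex weights:
constants are conserved exactly, outputs never leave the range of the
contributing sources, and an isolated spike is attenuated, never amplified.
The FWHM-overlap cut-off (instead of, say, ±3σ tails) makes resampling local
but slightly non-transitive: coarsening 1 nm → 10 nm → 100 nm agrees with
direct 1 nm → 100 nm to well under 1% only where the spectrum varies on
scales larger than the destination bandwidth; across a sharp red edge the
two routes can differ by a few percent. A destination band with no
overlapping source raises a named error rather than returning 0/0.

Even grids (`even_grid(lo, hi, fwhm)`) tile `[lo, hi]` with centres starting
at `lo + fwhm/2` — the phase that makes bands partition the interval.
Key-wavelength layouts (`key_band_spec()`) come in two modes: narrow-band
keeps the source sensor's native FWHM (1 nm spectrometer, 5.5 nm VNIR
camera, 12 nm SWIR camera); broad-band lets each band's half-width reach half
the distance to its nearest neighbouring key, i.e.
`FWHM = min(gap_left, gap_right)`, end keys using their single neighbour.

## Regression and key-wavelength identification

The estimator is PLS1 via NIPALS with mean-centred predictors and response.
No unit-variance scaling is applied — all predictors are reflectance in the
same units, and scaling would inflate noisy low-signal bands (a
standardising variant can be added by the user before fitting). One NIPALS
decomposition yields the whole nested coefficient path $b_1, \dots, b_K$, so
model selection over component counts costs one fit.

Cross-validation is 5-fold over samples, assigned by a seeded permutation.
Within each training partition an *inner* 5-fold cross-validation picks the
latent-variable count in 1–20 minimising pooled RMSE; selecting on the outer
validation fold would leak information into the reported accuracy. The model
is refit on the full training partition and the held-out fold predicted; the
package reports per-fold metrics and their average. Counts above
`min(n_train − 1, n_bands)` are capped with a warning. Each leaf ×
time-point is one sample by default; a `groups` argument keeps repeated
measures of a plant in one fold for users who prefer the conservative
design (repeated measures of one plant are correlated, so sample-level folds
slightly flatter the validation accuracy; with hundreds of samples the
difference is small).

Reported metrics: $R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ (negative
when the model is worse than the mean of the evaluated fold), RMSE, signed
bias $\overline{\hat y - y}$, and mean and median absolute errors, all in N%
units.

**Key-wavelengths.** The five fold coefficient vectors are averaged
pointwise; wavelengths at strict interior local extrema of the averaged
curve, ranked by coefficient magnitude, are the key-wavelengths. A run of
exactly equal values counts as one extremum at its centre band (relevant for
coarse grids; on noisy 1 nm data exact ties are measure-zero). A monotone
curve yields an empty set with a warning rather than an error.

**Cross-sensor application.** A consensus model — refit on all samples with
the median of the fold-selected component counts — can be applied to spectra
from another instrument after resampling them onto the model's grid
(`apply_cross_sensor()`). Prediction is affine, so a planted gain mismatch
between instruments surfaces as bias with a near-unit slope of predicted
versus true — the diagnostic signature that recalibration, not remodelling,
is needed.

## Vegetation-index baselines

`NREAI = (SD_r − SD_b)/(SD_r + SD_b)`, with `SD_b` and `SD_r` the integrals
of the first-derivative spectrum over the 490–530 nm blue edge and
670–737 nm red edge. The derivative uses central differences on the native
grid (one-sided at the ends) and integration the trapezoidal rule — for a
linear spectrum this gives exactly `(67 − 40)/(67 + 40) = 27/107`, the
closed form used as a test oracle. A constant spectrum makes both integrals
vanish; the index returns `NA` (an undefined-value marker) rather than
erroring.

The NDVI search evaluates `(r_i − r_j)/(r_i + r_j)` for every unordered
wavelength pair on the analysis grid and regresses N% on each index by
univariate least squares under the *same* seeded fold assignment as the
PLSR models, storing fold-averaged validation R². Cross-validated rather
than in-sample R² keeps the exhaustive search honest — with thousands of
pairs, in-sample R² rewards overfitting. Sign-flipping the predictor leaves
least-squares R² unchanged, so the matrix is symmetric and each pair is
computed once and mirrored; the per-spectrum NDVI matrix itself is
antisymmetric with a zero diagonal. Diagonal entries (constant predictor)
and pairs with undefined indices are `NA`.

## The synthetic-data generator

No public dataset accompanies the analysis, so the package ships a seeded
generator (`generator_config()`, `generate_cohort()`, `generate_cube()`,
`generate_ledger_for_cleaning()`) that emulates the *statistical structure*
the pipeline assumes:

- A fixed smooth continuum resembling green-leaf reflectance (visible trough
  with a green bump, sharp red edge, NIR plateau, SWIR decline), encoded as
  spline control points — not measured data.
- Gaussian absorption dips whose depths grow linearly with the sample's N%,
  centred by default at 676, 1517, 2106, 2180 and 2313 nm — chlorophyll and
  protein/N–H bands repeatedly implicated in nitrogen sensing. Widths default
  to σ = 10 nm (≈ 24 nm FWHM, typical of SWIR absorption features) and depths
  to 0.004–0.007 reflectance per unit N%.
- Nitrogen-independent confounder dips at the 1450 and 1940 nm water bands
  with uniformly random depths, multiplicative amplitude jitter
  (sd 0.02) emulating illumination/geometry variation, and additive Gaussian
  sensor noise (default sd 0.005 reflectance).
- N% drawn per treatment (25/50/100/200 mg N per kg soil) from Gaussians with
  means 2.0/3.0/4.0/5.5% and sd 0.6, clipped to the 1–7% window — spanning
  the plausible range for wheat leaves while leaving mass near the outlier
  boundaries.
- Optional splice offsets at configurable detector junctions (defaults 1000
  and 1800 nm, the nominal hand-over points of a three-detector full-range
  spectrometer).
- Image cubes with black background (flat 0.05), a blue marker rectangle, and
  leaf pixels from the cohort model with per-pixel noise; raw intensities are
  produced by *inverting* the calibration equation against generated dark and
  white frames, so calibration recovers the planted reflectance to machine
  precision.
- Ledgers with exact counts of under-weight leaves (< 100 mg, no laboratory
  N%), N% outliers (outside 1–7%) and acquisition errors, for testing the
  cleaning rules (600 − 42 − 8 − 7 = 543 survivors).

All randomness flows from one mandatory seed through named substreams, so
each artefact is reproducible in isolation and whole runs are byte-identical
under one seed.

**What the generator does not emulate** — and therefore what green tests do
*not* establish about real data: no radiative-transfer leaf optics (features
are additive Gaussians, real absorption is nonlinear in concentration and
water masks protein bands), no leaf geometry, shadow or specular effects
beyond a scalar amplitude jitter, no inter-band correlated noise, no
variety-specific spectral differences, and leaf/marker regions are rectangles
rather than leaf-shaped. Passing recovery tests show the *pipeline* is
correct and identifiable under its stated noise model; they do not certify
field accuracy.

## Numerical choices and degenerate inputs

- Wavelengths are nm floats; grid comparisons use an absolute tolerance of
  $10^{-6}$ nm; datasets refuse to mix grids rather than interpolate.
- Calibration guard $10^{-9}$; guarded elements are `NA` plus a mask, not an
  error, since dead reference pixels are routine.
- Spectral angle clamps its cosine to [−1, 1] before `acos`; zero vectors are
  errors (undefined direction), as are achromatic pixels in hyper-hue
  (callers map them to background).
- One-pixel markers cannot be oriented and raise a degenerate-geometry error.
- `ndvi` and `nreai` return `NA` markers for undefined values; regressions
  drop `NA` samples and error only when fewer than 3 remain.
- Extrema ties (plateaus) collapse to the centre index; ranking ties between
  distinct extrema break by wavelength for determinism.
- The NIPALS deflation stops early if the response is exhausted; shorter
  coefficient paths are padded with the last model during inner CV so every
  candidate count has a score.
- ENVI IO writes 64-bit IEEE floats (data type 5), little-endian, and checks
  the header-implied byte count against the file before reading.

## Problem sizes in the test-suite

The suite exercises the full pipeline at deliberately modest sizes chosen as
the smallest that demonstrate each property: cohorts of 12–300 samples on
1–20 nm grids, 60×60×51 image cubes, and experiment grids with 60–80 samples
across three emulated sensors. The default generator conditions (n = 300,
noise sd 0.005) drive the headline recovery checks: fold-averaged validation
R² ≥ 0.9 and at least 4 of the top-5 key-wavelengths within ±10 nm of planted
feature centres across three seeds. `scripts/acceptance.R` re-runs all of
these from a single command-line seed.

## Known limitations

- PLS1 only (single response); multi-response PLS2 is out of scope.
- No scatter corrections (SNV/MSC) or derivative spectroscopy beyond the
  derivative inside NREAI — deliberately matching the modelled workflow.
- The NDVI search is narrow-band only; broad-band NDVI saturates and was not
  modelled.
- Cross-sensor application assumes the target spectra were resampled onto the
  model grid; no spatial co-registration between cameras is attempted.
- The one-class SVM's `nu` floors the leaf-pixel miss rate; the majority
  cleanup mitigates but cannot recover clustered misses, so masks on very
  noisy scenes should be inspected.
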