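---
title: "Methods: NIR hyperspectral calibration of needle chlorophyll and water content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR hyperspectral calibration of needle chlorophyll and water content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firspec)
```

## The estimation problem

`firspec` estimates two physiological traits of conifer (Chinese fir)
seedlings from near-infrared reflectance spectra: needle leaf chlorophyll
content (LCC, mg of total chlorophyll per g of fresh needles) and needle
leaf water content (LWC, the water mass fraction `(M1 - M2)/M1`, stored as
a fraction and displayed as a percent). Both decline along a drought
gradient, and both leave signatures in the 870–1720 nm range: O–H overtone
water absorption near 970 and 1450 nm, and chlorophyll-linked N–H / C–H
overtone features near 1100 and 1190 nm.

The pipeline follows standard NIR chemometrics practice:

1. **Reflectance calibration.** Raw counts `I` are normalised against a
   white-panel frame `W` and a lens-capped dark frame `D` as
   `R = (I - D)/(W - D)` ([calibrate_reflectance()]). The result is
   invariant to common rescaling of all three images; pixels where
   `W = D` are a hard error reported by location, never silently skipped.
2. **Canopy ROI.** A brightness mask selects canopy pixels
   ([make_mask()]); the mean spectrum over the mask is the sample's
   spectrum ([extract_roi_mean()]).
3. **Preprocessing.** Savitzky–Golay smoothing, standard normal variate,
   or multiplicative scatter correction, compared as alternatives.
4. **Wavelength selection.** The successive projections algorithm (SPA)
   and competitive adaptive reweighted sampling (CARS) reduce the 512
   bands to a small informative subset.
5. **Calibration models.** PLSR (NIPALS), epsilon-SVR and a
   single-hidden-layer neural network, fitted on a stratified 70/30
   calibration/prediction split and compared by `R²` and RMSE on both
   sets.

## Canopy masking

The mask threshold (default 0.45) is a *minimum*: pixels at or above it
are kept, so the boundary is inclusive. The thresholded statistic is not
uniquely determined by how such workflows are usually described; we
default to the mean reflectance across all bands — a robust
brightness-like scalar — and expose a single-band variant
(`statistic = "band"`). No morphological cleanup is applied: on
well-separated scenes (bright canopy over dark background) thresholding
alone recovers the exact canopy set, and silent cleanup would mask
calibration problems.

## Preprocessing details

* **Savitzky–Golay** (default window 11 bands, polynomial order 2, no
  derivative) is plain smoothing; window and order are not critical in
  this range and are configurable. A derivative filter (`deriv > 0`) is
  available for workflows that prefer it. Edge bands are handled by the
  filter's truncated-window polynomial fits, so polynomials up to the
  filter order pass through unchanged everywhere — the property the test
  suite asserts at 1e-8.
* **SNV** standardizes each spectrum by its own mean and *population*
  standard deviation (divisor `n`). The convention matters only at the
  margins, but fixing it makes the two-band example `{0, 1} -> {-1, +1}`
  exactly reproducible.
* **MSC** regresses each spectrum on a reference by OLS and inverts the
  fitted affine map. The reference is the mean spectrum of the
  calibration set; it is returned with the result and must be passed when
  transforming prediction data, so that no prediction-set information
  enters the transform. `apply_preprocess(..., state = )` wires this
  through the pipeline automatically.

## Wavelength selection

**SPA** builds chains of minimally collinear bands: each step projects all
unselected band vectors onto the orthogonal complement of the chain and
appends the band with the largest residual norm (implemented by rank-one
deflation; the test suite verifies exact agreement with an explicit
projector oracle). Chains from every candidate start band and every size
`k` in `[1, 30]` are scored by the RMSE of a multiple linear regression,
by default on a seeded 80/20 holdout inside the calibration set (the
validation scheme is not dictated by the method; holdout is cheap and the
`validation = "none"` variant is fully deterministic). Ties prefer the
smaller subset, then the lower start index, for reproducibility.

**CARS** runs `N = 50` Monte-Carlo sampling runs with ten-fold
cross-validation scoring. Each run fits a PLS model on a random 80% of
the calibration samples (the per-run fraction is a convention, not a
derived quantity) and ranks the currently retained bands by the absolute
value of their PLS regression coefficients. The number of survivors is
enforced by the exponentially decreasing function `r_i = a e^{-k i}` with
constants fixed by the boundary conditions that run 1 retains all `p`
bands and run `N` retains 2 — the constants of the original CARS
formulation, adopted here because the schedule itself does not determine
them (`a = (p/2)^{1/(N-1)}`, `k = ln(p/2)/(N-1)`). The count conversion
uses a ceiling with a 1e-9 backoff so that floating-point noise at the
exact boundaries cannot inflate the count by one.

Adaptive reweighted sampling is implemented as *count-preserving*
weighted sampling: exactly the EDF-enforced number of bands is drawn
without replacement with probability proportional to `|coefficient|`.
A variant that draws with replacement and keeps the distinct bands was
considered and rejected: it shrinks the retained set roughly 37% below
the EDF schedule at every run, which contradicts the EDF's role of
*enforcing* the retention curve (and the diagnostic "number of sampled
wavelengths vs run" plot would no longer follow it). With the
count-preserving form, the recorded per-run retained counts equal the
EDF counts exactly, and the stochastic competition still lets
low-coefficient bands survive occasionally, as intended.

The PLS component count used inside CARS is selected once per call by
ten-fold RMSECV on the full calibration data (capped at 10) and reused in
every run; re-selecting per run multiplies cost roughly tenfold without
changing which bands win the competition in our experience with the
synthetic gradient. Each run's band set is scored by ten-fold RMSECV on
the full calibration set; the run with the lowest RMSECV is chosen, with
exact ties resolved toward the smaller subset.

## Calibration models

* **PLSR** is authored in-package as univariate NIPALS (R/pls.R): for a
  single response the weight vector of each component is the normalised
  covariance `X'y`, followed by score computation and rank-one deflation.
  With full components it reproduces ordinary least squares to 1e-6,
  which the tests use as an oracle. The component count defaults to
  automatic selection by ten-fold RMSECV, capped at `min(20, rank)`.
* **SVR** wraps `e1071::svm` (epsilon-regression, RBF kernel by default)
  with a grid search over `C ∈ {0.1..1000}`, `gamma ∈ {0.001..1}`,
  `epsilon ∈ {0.01, 0.1}` by five-fold CV. Inputs and target are
  standardized internally by the library using training statistics only;
  note this means the epsilon tube is `epsilon` wide on the
  *standardized* target.
* **ANN** wraps `nnet::nnet`: one hidden layer (default 10 units) with
  logistic activation and a linear output unit, trained by BFGS with
  weight decay (default 1e-4) as the regulariser — `nnet`'s native
  mechanism, used here in place of early stopping. Inputs and target are
  standardized with calibration statistics. `activation = "identity"`
  maps to a skip-layer network with no hidden units, which is exactly a
  linear model trained by the same optimiser; the tests use this collapse
  as an oracle against least squares. All randomness (initial weights)
  is seeded, so refitting with the same seed is bit-identical.

All three families share one predict contract: the model remembers its
training band names and aligns prediction inputs by band identity;
missing or unknown bands are an error naming the offending columns. Every
statistic used at predict time (scalers, MSC reference, selected bands,
hyperparameters) is frozen at fit time from calibration data.

## Split and metrics

The calibration/prediction split is stratified by drought group with
largest-remainder allocation of per-group counts, so the global fraction
is met exactly: 0.7 on 180 samples (five groups of 36) gives 126/54,
with every group contributing 25 or 26 calibration samples. Metrics are
the textbook forms `R² = 1 - SS_res/SS_tot` and
`RMSE = sqrt(mean((y - ŷ)²))`; LWC is computed on fractions throughout
and converted to percent only at display boundaries.

## The synthetic drought gradient

No public instrument dataset accompanies this problem, so the package
ships a generator ([synthetic_config()], [simulate_traits()],
[simulate_spectra()], [simulate_cube()]) that emulates the study design
the pipeline targets: 180 seedlings in five drought groups (D0–D56) of
36, group-mean LCC declining 2.4, 1.8, 1.2, 0.6, 0.1 mg/g and LWC 0.68,
0.55, 0.40, 0.25, 0.09 along the gradient. Within-group spread is
Gaussian with sd equal to 10% of the group mean — enough visible spread
without overlapping the extreme groups — truncated to physical bounds
(LCC ≥ 0, LWC ∈ [0,1]) by resampling so the distributions stay
interpretable.

Spectra follow a minimal generative model chosen to reproduce the
qualitative features the preprocessing steps exist to handle: a gentle
quadratic continuum; four Gaussian absorption features (970/1450 nm
driven linearly by LWC, 1100/1190 nm by LCC); per-sample affine scatter
(gain ~ N(1, 0.05), offset ~ N(0, 0.02)) — which also makes the
effective continuum coefficients vary per sample, giving MSC/SNV
something real to remove; and additive Gaussian noise (sd 0.005),
clipped to (0, 1.2]. With scatter and noise disabled the map is
deterministic and injective in `(lcc, lwc)`, which the tests check by
brute force on a trait grid.

`simulate_cube()` wraps one sample's spectrum into a small scene —
canopy disk over dark background with matching white/dark frames — so
the cube I/O and masking stages are testable end to end against known
truth.

What the generator does *not* emulate: radiative-transfer leaf optics
(no PROSPECT-style realism), illumination geometry, sensor PSF, or
band-to-band correlated noise. Passing tests on synthetic data therefore
demonstrate that the chain of algorithms is implemented correctly and
recovers planted signal under realistic noise and scatter — not that any
particular accuracy will be attained on real instrument data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full 180 × 512
configuration for the end-to-end property (prediction `R² ≥ 0.9` for
both traits with SG → SPA/CARS → PLSR; a full run takes seconds to tens
of seconds) and reduced instances (64 bands, 30 samples) for unit
properties, keeping the suite fast without weakening any contract.
Other numerical choices: SPA treats columns whose residual norm falls
below 1e-10 of the largest as linearly dependent and truncates the chain
with a warning; CARS adds 1e-12 to sampling weights so exactly-zero
coefficients keep a vanishing but valid probability; MSC rejects fitted
gains below 1e-12 as degenerate; the ENVI reader supports float32/float64
and BSQ/BIL, and round-trips float64 bit-exactly.

## Known limitations

* SPA evaluates all start bands by default; on much larger grids a
  subsample of starts (`starts =`) trades optimality for speed.
* The SVR grid is deliberately small; serious use on real data would
  widen it.
* CARS subset sizes and chosen run numbers are data-dependent; on
  synthetic data they need not match sizes reported for any particular
  field dataset, and the shipped reference wavelength lists
  ([reference_wavelengths()]) are provided for comparison, not as a
  correctness target.
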