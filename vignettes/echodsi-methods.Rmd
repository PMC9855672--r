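---
title: "Methods: biophysical features and disease-specific imaging for breast ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysical features and disease-specific imaging for breast ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(echodsi)
```

This vignette is the package's own account of the models it implements,
the free parameters that matter, the numerical choices made where the
method leaves room, and what the synthetic-data tests do and do not show
about real data.

## The processing chain

Clinical scanners convert beamformed RF echoes to IQ/envelope data and
then to a log-compressed B-mode display.  Each conversion discards
information: the envelope loses phase and frequency content, log
compression distorts amplitude statistics.  `echodsi` therefore extracts
features at the stage where each is best defined:

* **RF stage** — H-scan spectral analysis (frequency content is only
  present here);
* **envelope stage** — Burr amplitude-statistics fitting (log compression
  would distort the histogram);
* **log-compressed stage** — B-scan and margin texture statistics (these
  are display-domain quantities);
* **contour** — convex-hull boundary roughness.

Coordinates everywhere: row = axial sample, column = scanline, 0-based
pixel coordinates for contours and masks; the speed of sound is fixed at
1540 m/s for depth–time conversion, so the axial pitch is `0.77/fs` mm at
a sampling rate of `fs` MHz.

## Envelope and B-mode

The envelope is the per-scanline magnitude of the FFT-constructed analytic
signal.  Scanner vendors demodulate with proprietary IQ pipelines; the
analytic signal is the standard mathematically equivalent stand-in and is
unit-tested against pure and gated tones.  Log compression follows the
conventional B-mode mapping `20 log10(A / A_max)` clipped to a
`dynamic_range` (default 60 dB) and scaled to `[0, 255]`; the formula is a
package choice (the display convention is not unique) and both the range
and the 8-bit mapping are configurable.

## Zone-wise attenuation compensation

Tissue attenuates high frequencies faster, red-shifting spectral content
with depth and biasing any depth-dependent spectral feature.  Before
H-scan analysis the frame is split into `n_zones = 10` contiguous axial
blocks (remainder samples join the deepest zone) and zone `z`, with mean
depth `x_z` cm, is amplified by `10^(alpha · f0 · x_z / 20)` with
`alpha` in dB·MHz⁻¹·cm⁻¹ (breast default 1.0, center frequency default
9.4 MHz).  Two choices deserve note:

* the per-zone gain is a **scalar at `f0`**, which matches the printed
  form of the correction this package follows; a frequency-dependent mode
  (`10^(alpha · |f| · x_z / 20)` across the zone spectrum) is provided
  because it is the physically complete version and flattens the H-scan
  depth trend further;
* the gain is applied to the amplitude (not power) spectrum — the
  dB→linear conversion uses `10^(dB/20)`.

## H-scan color level

A bank of `n = 256` Gaussian bandpass filters with peak frequencies
equally spaced over 5.2–12.4 MHz (spacing `7.2/255 ≈ 0.028` MHz) is
applied per scanline in the frequency domain.  Each filter is normalized
to unit spectral energy so that no filter wins the matched-filter
comparison merely by admitting more bandwidth.  At each pixel the color
level `C` is the index of the filter whose output envelope is maximal;
ties break toward the lower index, making the map deterministic.  The
filter output is the envelope of the filtered analytic signal: the raw
filtered RF oscillates through zero, so a per-sample argmax on it would be
ill-defined.

Free parameter: the common spectral standard deviation `sigma_f` (default
1.0 MHz, the order of the imaging pulse bandwidth).  It is not prescribed
by the method and genuinely matters — narrow filters sharpen frequency
discrimination but amplify speckle noise in the argmax — so results should
always be reported together with `sigma_f`.  The printed filter spacing in
the source literature (2.8 × 10⁻¹ MHz) is inconsistent with 256 filters
spanning 5.2–12.4 MHz; this package honors the endpoints and count, which
force a spacing of ≈ 2.8 × 10⁻² MHz, and treats the printed value as a
typographical slip.  No despeckling is applied before the argmax.

The lesion-level features are the mean and population standard deviation
of `C` within the (smoothed) lesion mask.

## Boundary roughness dA/A

`dA/A = (convex hull area − contour area) / contour area`, computed on
the **raw** segmentation contour (smoothing would erase exactly the
roughness being measured).  The hull comes from `grDevices::chull`, areas
from the shoelace formula; the measure is rotation- and scale-invariant
and zero exactly for convex contours.  A brute-force hull (all point
subsets) is the test oracle for polygons up to 12 vertices, including a
hand-computed plus-sign example with `dA/A = 0.4`.

## Margin bands and texture statistics

The inner/outer margins are the rims removed/added by morphological
erosion/dilation with a disk whose radius is half of 10% of the lesion
length, with *length* defined as the maximum Feret diameter of the
contour — the reading adopted here of "margin length at 10% of the lesion
length" (total band width = 10%, split 5% in / 5% out).  The disk is
Euclidean in physical (mm) coordinates: on the RF sample grid pixels are
strongly anisotropic (≈ 0.02 mm axial vs 0.2 mm lateral), and a pixel-disk
would be a physical sliver whose erosion empties any realistic lesion.  On
isotropic grids this reduces to the classical pixel disk
(`r = round(5% · Feret)`), which is what the unit tests check.

Texture statistics (mean and population STD of the `[0, 255]` intensity)
are computed inside the lesion and over the union of the margin bands.
For these — and for the Burr fit and H-scan mask — the contour is first
smoothed by two Chaikin corner-cutting passes, mirroring the use of an
approximated boundary for everything except the shape feature itself;
whether margin statistics should use raw or smoothed boundaries is not
fully specified upstream, and the smoothed mask is used here.

## Burr speckle model

Envelope amplitudes in many soft tissues follow the Burr law
`P(A) = 2A(b−1) / (λ²[(A/λ)² + 1]^b)` with scale `λ > 0` and power-law
exponent `b > 1`; `b` falls as the scatterer distribution departs from the
fully-developed-speckle regime (heavier tails), and `λ` scales with gain.
The closed-form CDF `F(A) = 1 − [(A/λ)² + 1]^{1−b}` yields an inverse-CDF
sampler used as the generative oracle in tests.

Fitting is nonlinear least squares of the density against an equal-width
histogram whose bin count follows the *sampling-rate* rule
`n_bins = max(8, round(rate · N))` with `N` the number of envelope samples
in the lesion; the default rate is 10%, at which fitted parameters are
stable (coefficient of variation across rates 2–40% well below 5%) while
R² is still high — R² decays as rates grow because Poisson noise per bin
grows.  Numerical choices:

* **Histogram range.**  The upper edge is the data maximum capped at
  40 dB above the median amplitude.  For heavy-tailed regimes (`b ≤ 2`)
  the raw sample maximum sits orders of magnitude beyond the distribution
  scale and equal-width binning to the maximum collapses the informative
  bins (pilot fits at `b = 1.5` mis-estimated `λ` by > 1000%); the cap is
  inactive for the light-tailed amplitudes typical of tissue.
* **Weighting.**  Unweighted least squares on the density heights is the
  default.  A Poisson-weighted mode exists but measurably biases the fit
  upward in both parameters (empty tail bins get enormous weights), so it
  is not the default.
* **Bounds and starts.**  `λ ∈ (0, ∞)`, `b ∈ (1, 50]` (the upper bound
  prevents divergence toward the Rayleigh limit), starting at
  `λ₀ = median(A)`, `b₀ = 2`, with a small grid of fallback starts before
  failure.
* R² is `1 − SSE/SST` over the histogram heights.

## Combining features into a malignancy score

Features are standardized per-feature (means and SDs frozen on training
data — obligatory, since color levels live on 1–256 and `dA/A` near 0).
Three combiners are implemented:

* **PC1** — the top principal component, sign-oriented so the
  malignant-class mean exceeds the benign; contributions are normalized
  absolute loadings (a variance-weighted multi-component variant is
  available).  Linear, fastest.
* **Projection** — inner product with the unit benign→malignant centroid
  direction in standardized space.  The reference-direction formula is a
  package definition (the upstream method defines projection against a
  disease trajectory without giving a formula for the two-class case).
* **SVM distance** — signed decision value of a Gaussian-kernel
  soft-margin SVM, `(box, γ)` selected by seeded stratified 5-fold CV over
  `box ∈ {0.1, 1, 10, 100}`, `γ ∈ {0.01, 0.1, 1, 10}`, ties toward the
  smaller box then smaller γ (the smoother hyperplane).  The decision
  value is zero exactly on the hyperplane and its sign is the predicted
  class; it is a monotone surrogate for the geometric separation.  A
  `"geometric"` mode returns the Euclidean distance to the nearest point
  of the decision surface, found by deterministic ray search + bisection,
  and is validated against a dense-grid oracle; it is an order of
  magnitude slower and reserved for visualization-grade output.  The SVM
  is trained on all five standardized features by default (the
  alternative of training on three principal components is a
  visualization variant, not the default).

Feature-subset selection enumerates all `2⁹ − 1 = 511` nonempty subsets
and maximizes in-sample AUC of the chosen scorer; enumeration order
(size, then lexicographic) plus strict improvement makes ties resolve
toward smaller subsets.  For subset scoring the SVM uses fixed
`box = 1, γ = 1/m` rather than the full CV grid — selection cost, not
performance, dominates that choice.

## DSI rendering

Scores are clipped to `(d_lo, d_hi)` — by default the 5th/95th
percentiles of the training scores, stored per combiner — and mapped
linearly to a probability of malignancy in `[0, 1]`.  The H-scan color
level is the only localized feature, so the per-pixel score substitutes
the pixel's color level into the lesion's global feature vector; each
distinct level is scored once and looked up, which makes equal levels map
to bit-identical scores.  Maps are smoothed within the lesion by a 5 px
median filter then a Gaussian (σ = 2 px), both mask-aware: windows
renormalize over in-lesion pixels so the boundary is not darkened, and
the output range never exceeds the input range.  Two 256-entry colormaps
ship as code and CSV export (green→red for the score bar, light-blue→red
for overlays, the default); the probability-to-index lookup is monotone,
and rendering is a pure function (identical inputs give byte-identical
PNGs).  The displayed color encodes the clipped probability, not the raw
combined parameter.

## Evaluation protocol

* AUC is the Mann–Whitney statistic with half credit for ties (exactly
  the brute-force pairwise concordance); the 95% CI uses DeLong's method
  (seeded bootstrap available).
* Accuracy/sensitivity/specificity are computed at a threshold fitted by
  Youden's J **on training scores only** and frozen; the threshold rule
  is a package choice, declared and configurable.
* Per-feature class separation is tested by one-way ANOVA with the
  conventional star notation (`ns` p > 0.05 through `****` p < 0.0001).
* Cohorts are split into five seeded stratified 70/30 train/test sets;
  all fitting (standardizer, PC1, reference, SVM, clipping limits,
  threshold) happens on the training side of each split.  Stratification
  is a package choice that prevents empty-class folds at small cohort
  sizes.
* Lesion-size stratification filters to `area > A` (strict) for
  `A = 0, 0.1, …, 1.0` cm² and recomputes all metrics per threshold,
  flagging thresholds that leave fewer than two cases per class rather
  than dropping them silently.

## The synthetic cohort generator

The generator exists so that every operator upstream of it can be tested
against data with known structure.  It is a 1-D convolution model: point
scatterers drawn uniformly at 600/mm² (≈ 45 per resolution cell at the
default geometry — comfortably inside the fully-developed-speckle regime,
where the background envelope passes a Kolmogorov–Smirnov test against
Rayleigh) are binned per scanline and convolved with a Gaussian-modulated
cosine pulse; zone-wise `10^(−α|f|x_z/20)` filtering models attenuation
and white noise models the floor.  Class-conditional knobs and their
strong-effect defaults:

| knob | benign | malignant | exercises |
|---|---|---|---|
| lesion spectral content | 8.5 MHz | 10.5 MHz | H-scan color level |
| echogenicity ratio | 1.0 | 0.5 | B-scan intensity |
| boundary roughness | 0.05 | 0.5 | dA/A |
| reflectivity law | Gaussian-like (b 3.5) | heavy-tailed (b 2.0) | Burr b, texture STDs |

Lesion contours are star-shaped polygons: ellipse radii perturbed by
circularly smoothed Gaussian noise with amplitude `roughness × mean
radius` (radius floor-clamped at 8% of the ellipse radius), which keeps
polygons simple by construction and makes expected `dA/A` monotone in the
roughness knob.  The Burr reflectivity mapping is monotone, not an
analytic identity: drawing scatterer amplitudes from a Burr law with the
requested `b` produces envelope fits whose `b` ordering follows the
request, which is what the class-separation tests require.

Default geometry: 96 lines × 1024 samples at `fs = 40` MHz (axial pitch
19.25 µm), 0.2 mm lateral pitch, lesions of 2.5–4.5 mm semi-axes
(≈ 0.2–0.6 cm²) at mid-depth, transmit 9.4 MHz with 50% fractional
bandwidth, attenuation 1 dB·MHz⁻¹·cm⁻¹, 1% noise floor.  The acquisition
geometry is a package convention — no standard frame size exists for this
kind of study — and problem sizes throughout the tests (80-case
acceptance cohort, 100-frame speckle checks, 5 × 10⁴-sample fit
recoveries) were chosen as the smallest that make the statistical
assertions stable.

**What passing tests do not show.**  The generator has no diffraction,
beamforming, elevational focus, phase aberration or anatomy; echogenicity
and spectral content are uniform within a lesion; labels are perfectly
correlated with the generating knobs.  The strong-effect defaults make
the classes fully separable by design, so AUC = 1 on synthetic cohorts
demonstrates the pipeline's correctness (monotone class contract,
combined-beats-single pattern), not clinical performance.  Real-data
claims require real cohorts.

## Known limitations

* The signed decision value is not a calibrated probability; the
  clipped linear mapping is a display convention, deliberately free of
  clinical claims (probability calibration is out of scope).
* The Burr fit assumes the lesion contains enough envelope samples
  (≳ 200) and positive spread; tiny lesions at coarse geometries will
  fail loudly rather than return noise.
* The geometric SVM distance is approximate (ray search); its
  guarantees are only those verified against the grid oracle.
* `fit_pc1` requires at least as many cases as features; cohorts smaller
  than six cases cannot train the default five-feature model.
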