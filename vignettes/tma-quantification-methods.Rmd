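---
title: "Methods: quantitative multiplexed immunofluorescence for TMA cores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative multiplexed immunofluorescence for TMA cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`tmaquant` implements a quantitative analysis chain for tissue-microarray
(TMA) cores imaged in four immunofluorescence channels — WNT4 (Alexa Fluor
405), MMP7 (FITC), cyclin D1 (Cy3) and c-MYC (Cy5), four proteins of the
Wnt signalling network studied in penile squamous cell carcinoma. The chain
has four stages:

1. **Synthetic cohort generation** — seeded multi-channel 16-bit core images
   with controllable group intensity structure and pixelwise inter-channel
   correlation, standing in for slide-scanner data that is not publicly
   deposited.
2. **Threshold segmentation and quantification** — median-to-maximum
   threshold calibration and per-core mean gray values.
3. **Co-localization** — background-subtracted Pearson coefficients between
   channel pairs within regions of interest (ROIs).
4. **Group statistics** — fold changes and Mann-Whitney U contrasts across
   control, grade I and grade II tissue classes.

Staining chemistry, scanner acquisition, deconvolution, and pathological
grading are out of scope: the package starts from pixel data.

# The synthetic cohort generator

## What it emulates

Each tissue class (control, grade I, grade II) is characterised by a
per-channel distribution of *per-core expected intensities*: a core's mean
gray value is drawn from a normal distribution, truncated at zero, with the
class mean and SD. The defaults are the published control and
malignant-group summaries (mean gray value ± SD per protein); both tumor
grades share the malignant values because per-grade means are not published.
Truncation matters: the published SDs are roughly half the means, so an
untruncated normal would produce negative intensities with non-negligible
probability.

The default cohort sizes mirror the study: 37 control, 82 grade I and 18
grade II cores (137 in total) from 101 patients; grade III is excluded
because the study held only two such cores and used them in no contrast.
Patients are assigned to cores round-robin within class (18 control and 83
malignant patients).

## Image construction

A core is a disc of radius `core_radius_px` (default 110 px) centred in a
`image_size_px`² image (default 256²); the disc mask covers ≈ 38 000 pixels,
and its pixel count stays within 1% of πr² for radii ≥ 50 px. Inside the
mask, each channel's pixel field is built as follows:

1. Four independent standard Gaussian white-noise fields are smoothed with a
   separable Gaussian kernel of scale `smoothing_length` (default 3 px),
   giving spatially coherent texture.
2. The smoothed fields are **whitened empirically within the mask**: their
   sample covariance is forced to the identity. They are then mixed by the
   symmetric eigen square root of the class's target 4×4 correlation matrix.
   Because whitening precedes mixing, the *sample* pixelwise inter-channel
   correlation within the mask equals the target exactly, before noise and
   quantization — not merely in expectation. Target matrices are validated
   (unit diagonal, entries in [−1, 1], positive-semidefinite) and rejected
   with a diagnostic naming the offending class otherwise.
3. Each field is scaled to SD `pixel_sd` (default 300 gray levels) and
   shifted to the core's drawn expected intensity; unsmoothed pixel noise of
   SD `noise_sd` (default 30) is added; values are clipped to [0, 65535] and
   rounded to integers. Outside the mask, background pixels are drawn at
   `background_mean` ± `background_sd` (defaults 50 ± 10 — the study never
   states non-tissue levels, so these are package choices).

Additive noise attenuates the imposed correlation by the factor
`pixel_sd² / (pixel_sd² + noise_sd²)` (≈ 0.99 at the defaults), and clipping
can attenuate extreme configurations further; correlation-recovery tests
therefore use a ±0.05 band. Defaults keep pixel distributions well inside
the 16-bit range so clipping is rare.

Determinism: each core derives its own seed as a hash of
`(master seed, class, core index)`, so a cohort is reproducible core by core
and under partial regeneration. `simulate_core()` reseeds the global RNG
(with the Kinderman-Ramage normal generator, chosen for speed at this draw
volume; the whitening step pins the fields' first two sample moments
regardless of generator tail quality).

## What it does not emulate

No optics: no point-spread function, no autofluorescence, no spectral
bleed-through, no uneven illumination, no tissue morphology (nuclei,
stroma). Within-core texture is a stationary Gaussian field, which is far
tamer than real tissue. Consequently, passing recovery tests demonstrates
that the *analysis chain* is correct and unbiased under the generating
model — not that it is robust to the artefacts of real slides.

One visible consequence: real cores have heavy-tailed within-core intensity
distributions, so the published median-to-maximum segmentation rule still
captures pixels in every core. Under the Gaussian generator, within-core
spread (`pixel_sd`) is small relative to between-core differences, and a
dim core can fall entirely below the pooled median; its mean gray value is
then flagged missing rather than fabricated, and group contrasts report the
affected cells as `NA` with a warning.

# Threshold segmentation and quantification

Calibration follows the published median-to-maximum rule: for each channel,
the pixels of the calibration cores are pooled, and the segmentation
interval is [pooled median, pooled maximum]. Decisions the source left
open, resolved here:

* The median is computed over **pooled pixels**, not per-core medians
  ("across the whole sample set"); with an even count it is the mean of the
  two middle values.
* Thresholds are **per channel**, matching the separate optimization of the
  four fluorophores.
* The study quantified squamous cells only; no cell classifier exists here,
  so calibration restricts to tissue by a background floor — by default an
  Otsu split of the pooled histogram (`background_floor = "otsu"`), with
  `"none"` and numeric floors available. This is a documented stand-in, not
  a cell-type model.

`quantify_core()` segments pixels with `lower ≤ value ≤ upper` and reports,
per channel: `mean_gray` (mean over segmented pixels — thresholding would be
pointless if the mean were taken over all pixels), `integrated_per_area`
(segmented intensity sum ÷ segmented area; pixel units unless a physical
pixel size is set — the source does not define this quantity, so both are
reported), `segmented_px` and `segmented_fraction` (denominator: all raster
pixels, which keeps the fraction in [0, 1] by construction). A channel with
no segmented pixels yields `NA`, never zero.

# Co-localization

`estimate_background()` implements the "Gaussian minimum" background: the
minimum of the Gaussian-smoothed channel (default scale 5 px — the source
names the method but no parameters). Smoothing suppresses isolated extreme
pixels, so the minimum tracks the flat background level. Per channel, the
scalar background is subtracted and negative pixels are clamped to zero;
the clamped fraction is reported because clamping can bias the coefficient.

`pearson_coloc()` computes the sample Pearson correlation between two
channels over an ROI (0-based, half-open rectangles). A zero-variance
channel yields a missing value with the recorded reason, not an error. The
estimator is checked against a naive two-pass oracle to 1e-10, and is exactly
symmetric and invariant under positive affine rescaling.

ROI placement on real slides was manual (pathologist-guided, 4–16 ROIs per
image); `roi_grid()` is the deterministic synthetic stand-in: square ROIs on
a regular grid, kept when ≥ 99% of their pixels exceed an Otsu
tissue/background split. The study computed coefficients on deconvolved
confocal Z-projections; this package operates on single-plane images and
treats deconvolution as out of scope.

A sampling note that shaped the tests: with spatial correlation scale σ, a
w×w ROI holds only ≈ w²/(4πσ²) independent patches, so ROI-level
coefficients at the default σ = 3 are noisy for 32-px ROIs (≈ 9 effective
samples). Property tests that aggregate ROI-level coefficients therefore
simulate with σ = 1; whole-mask recovery is exact by construction at any σ.

# Group statistics

`mann_whitney_u()` follows the conventions used for the published contrasts:

* U from midranks (average ranks for ties); two-sided p throughout (the
  source reports `p <` thresholds without sidedness; two-sided is the
  conservative default).
* For two tie-free groups of ≤ 8 observations, the exact permutation
  distribution is enumerated; otherwise the normal approximation with
  tie-corrected variance and continuity correction is used. Exhaustive
  enumeration shows the approximation is within 0.03 of the exact two-sided
  p for group sizes ≥ 5 (worst case 0.017); at sizes 3–4 the worst case
  reaches 0.031–0.038, which is why the exact branch covers them.
* All values tied across both groups degenerate to p = 1.

`fold_change()` is the case-group mean over the control-group mean, rounded
half away from zero to one decimal — the printed fold-increase convention.
The printed Wnt4 fold (1.9) is *not* reproducible from the printed means
(7192/3620 = 1.99 → 2.0); the discrepancy is reported, not reconciled.

`compare_intensities()` contrasts per-core mean gray values per channel
(default contrasts: control vs all-malignant, control vs each grade, grade I
vs grade II); `compare_coloc()` contrasts per-ROI Pearson coefficients per
channel pair, reporting median differences instead of fold changes (a
correlation has no ratio scale). No multiple-testing correction is applied,
matching the per-comparison reporting of the source; the number of
comparisons is annotated. `summarize_box()` reports median, quartiles and
the 99th percentile (linear interpolation between order statistics),
matching the published box-plot annotations.

A power fact worth knowing: at the published c-MYC parameters
(3109 ± 1969 vs 4951 ± 2304, n = 37/102) the Mann-Whitney test has ≈ 80%
power at α = 0.001 — rank tests are invariant to the affine intensity
scale, so no generator geometry changes this; it is intrinsic to the
published effect size. Recovery simulations for c-MYC reach p < 0.001 in
roughly four seeds out of five, while the other three proteins do so
essentially always.

# Numerical and design choices

* **Gaussian smoothing** is implemented as multiplication by cached banded
  (4σ-truncated, row-renormalized) sparse smoothing matrices — exact at the
  borders, faster than FFT filtering at core-image sizes, and validated
  against an independent Gaussian filter implementation on interior pixels.
* **Problem sizes in tests**: cohort recovery runs 50 seeds of the full
  139-core cohort at 256² px; correlation recovery uses ≥ 10⁴ mask pixels;
  ROI-level power and type-I simulations use 96–128 px cores. These sizes
  make every stochastic check sharp enough to detect implementation bias
  while keeping the whole suite runnable on a laptop.
* **Ties and degenerate inputs**: empty manifests warn and return empty
  tables; unreadable cores are skipped row-wise with a warning and recorded
  in an `errors` attribute; an all-background channel is a flagged result,
  not an error.
* **CSV conventions**: comma-separated, mandatory header, UTF-8, `.`
  decimal, missing values as empty fields. Multi-page TIFFs are 16-bit
  grayscale with the fixed page order WNT4, MMP7, CD1, cMYC.
* **Determinism**: the whole pipeline is a pure function of (config, seed):
  rerunning `run_pipeline()` with the same configuration produces
  byte-identical result tables.

# Known limitations

* The generator's stationary Gaussian texture understates real within-core
  heterogeneity; calibrated-threshold behaviour on real slides will differ
  (see above).
* The squamous-cell restriction of the source is approximated by an
  intensity floor, not a cell classifier.
* Single-plane only; stacks must be reduced (e.g. maximum-intensity
  projection) before analysis.
* No Manders or Costes coefficients, and no Costes randomization test; the
  Pearson coefficient is the only co-localization measure, as in the source
  analysis.
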