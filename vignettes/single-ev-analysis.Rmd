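---
title: "Single-EV co-expression profiling and the CD98+ EV Index: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-EV co-expression profiling and the CD98+ EV Index: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevtools)
```

## The problem

Extracellular vesicles (EVs) released by tumor cells carry surface
proteins of their parent cell, which makes them attractive liquid-biopsy
analytes. Two measurement modalities are covered by this package:

1. **Multiplex single-EV fluorescence imaging.** Vesicles are deposited
   on a slide, labeled with an amine-reactive total stain plus
   fluorophore-conjugated antibodies against CD63, CD9 and CD98, and
   imaged at 20x in four channels. Each vesicle is far below the
   diffraction limit, so it appears as a point-spread-function (PSF)
   shaped spot. The scientific output is the co-expression profile: for
   every detected (total-stain positive) vesicle, which of the 2^3 = 8
   marker combinations it carries.
2. **The CD98+ EV Index.** Per subject, CD98-carrying vesicles are
   counted in antibody-coated wells on an optical disc that also carries
   PBS negative-control wells; a particle-tracking measurement provides
   the total EV concentration. The index is the control-normalized count
   divided by the concentration (in units of 10^9 particles/mL), and is
   evaluated as a classifier separating early hepatocellular carcinoma
   (HCC) from healthy plasma.

Neither raw images nor patient tables are publicly deposited, so both
stages ship with synthetic-data generators whose defaults are planted at
the published operating points; every analysis operation is then tested
by parameter recovery against the planted truth and by independent
oracles (brute-force scans, closed forms, rank statistics).

## The imaging simulator

`field_spec()` + `simulate_field()` generate one 512 x 512 px field with
`n_evs = 269` spots (three fields ≈ 807 vesicles, the published
profiling denominator). Key choices, all exposed as parameters:

* **PSF**: isotropic 2-D Gaussian, sigma 1.3 px, truncated at 4 sigma
  and normalized to unit sum over the truncation window, so a spot's
  amplitude equals its integrated signal in ADU. The source study states
  no pixel scale or camera model; sigma 1.3 px is a typical
  diffraction-limited width at 20x on an sCMOS sensor.
* **Amplitudes**: the total-stain amplitude is log-normal
  (mean 3000, sd 1100 ADU) to mimic the size/labeling heterogeneity of a
  145–165 nm vesicle population; marker amplitudes are truncated normal
  (mean 1800, sd 350 ADU), a typical antibody-conjugate brightness at
  which a present marker sits far above the positivity threshold while an
  absent marker has exactly zero planted signal. A marker channel
  amplitude is positive iff the vesicle carries that marker.
* **Noise**: Poisson shot noise on signal + background (100 ADU per
  channel), then Gaussian read noise (sd 2 ADU) — a generic sCMOS model.
  Both can be switched off, which the exactness tests use.
* **Placement**: rejection sampling with an 8 px minimum separation
  (≥ 6 PSF sigma), reflecting that the imaged suspensions were verified
  not to aggregate; spots therefore do not merge under the default
  geometry. A deliberate sub-PSF pair is used in the tests to document
  the merge limitation.
* **Crosstalk**: a 4 x 4 mixing matrix applied to the noiseless spot
  signals (identity by default) supports bleed-through stress tests.
* **Combination frequencies**: `default_combination_freqs()` is the
  unique 8-vector consistent with the published marginals (77.7% CD63+,
  26.9% CD9+, 33.0% CD98+), the 22.1% triple-negative fraction and the
  CD98-negative CD63+/CD9+ subpopulations (44.9%/6.7% of all vesicles).

What the simulator does **not** emulate: optical aberrations,
super-resolution (STED) detail, z-structure, photobleaching, aggregated
or overlapping vesicles, autofluorescent debris, illumination gradients.
Passing recovery tests therefore demonstrates that the analysis chain is
unbiased under an idealized-but-noisy widefield model, not that it is
robust to every real-microscope artifact.

## Segmentation

Detection happens only in the total-stain channel
(`segment_field()`):

1. 256-bin histogram over the observed intensity range (`[min, max]` of
   the field, not the dtype range, so low-contrast fields keep full bin
   resolution).
2. **Global triangle threshold**: with the histogram peak at
   `(b_p, h_p)` and the farthest non-empty bin on the longer-tail side
   at `(b_e, h_e)`, the selected bin maximizes the perpendicular
   distance from `(b, h_b)` to the peak–tail chord, restricted to bins
   strictly between them. Tie-breaks are documented and tested: peak
   ties take the lowest bin, tail-length ties take the higher-intensity
   side, distance ties take the bin nearest the peak. The threshold is
   the upper edge of the selected bin and pixels are foreground iff
   strictly above it, which makes the whole chain invariant to adding a
   constant to the image. A constant image has no second histogram bin
   and raises a degenerate-histogram error.
3. Binary opening (disk of radius 1) and hole filling; the opening
   removes single-pixel shot-noise specks.
4. Connected components at 8-connectivity (in-package flood fill;
   4-connectivity available), then an area gate of [2, 80] px².
   The lower bound discards residual specks. The upper bound was set
   from the PSF geometry: with noise disabled the triangle threshold
   sits just above background, so a bright spot's above-threshold
   footprint approaches the full 4-sigma disc, about 85 px² at
   sigma 1.3; a cap much below that silently discards the brightest
   vesicles, while anything larger can only be a merged cluster.

Coordinates are 0-based `(x = column, y = row)` throughout the exported
tables, matching the ground-truth CSV schema.

## Positivity and co-expression

`measure_evs()` transfers the label map unchanged to every channel, so
one pixel set per vesicle is used in all four channels. Per channel:

* **Local background**: median over the annulus between the `r_in = 2`
  and `r_out = 5` px dilations of the component, excluding pixels of any
  foreground component (a neighbor can therefore never contaminate the
  estimate); the median, not the mean, for robustness to stray signal.
  An empty annulus falls back to the global image median (logged).
* **Corrected mean** = component mean − local background, floored at 0.
* **Positivity**: corrected mean > `k_sigma` x the robust background sd
  (MAD x 1.4826 of all pixels outside the dilated foreground), with
  `k_sigma = 3`. The source study never states its decision rule; a
  3-sigma rule over a robust noise scale is the standard detection
  convention and is exposed in `positivity_params()`. When the
  background sd is exactly zero (noise-free renders) the rule degrades
  to "strictly above zero", which makes noise-free recovery exact.

`coexpression_table()` tabulates the eight combinations over all
detected vesicles — the denominator is total-stain positive vesicles,
and the triple-negative class is retained — pooling raw counts across
fields (not averaging per-field fractions), matching the published
"n = 807 from three 20x images" convention. `line_scan()` provides
bilinearly interpolated multichannel intensity profiles for
co-localization figures.

## The cohort generator

`cohort_spec()` + `simulate_cohort()` emulate a 50 healthy / 136
early-HCC cohort:

* The per-subject **true index** is log-normal within group.
  `lognormal_from_median_iqr()` maps a published median/IQR summary to
  `(mu, sigma)`: `mu = log(median)` and sigma solves
  `median * (e^{z sigma} − e^{−z sigma}) = IQR`, `z = qnorm(0.75)`, by
  bracketed root finding refined to `|f| < 1e-10` (the closed form
  `asinh(IQR / 2 median) / z` serves as the independent test oracle).
  A two-parameter positive, right-skewed law is the minimal model
  consistent with the published summaries (HCC IQR 16.405 far exceeds
  the 9.761 median).
* **Counts**: the latent sample-well rate is
  `index x concentration / 10^9 + control_mean`; observed counts are
  Poisson. Each 16-well disc carries 2 PBS control wells
  (Poisson around `control_mean = 20`), shared by the 14 sample wells
  on that disc. The number of control wells per disc is not published;
  2 is the package default and configurable.
* **Concentration**: log-normal with median 10^10 particles/mL
  (sd 0.5 log units), a typical plasma-EV range; with the 10^9 scale
  this puts indices in the published single-digit range.
* **Covariates**: sex/smoking/alcohol frequencies are the published
  group rates; ages are normal around the published median with
  sd = IQR/1.349. Covariates are independent of the index within group,
  mirroring the published null associations. AFP (log-normal, median
  20 ng/mL, heavy tail) and tumor size exist only for HCC subjects;
  healthy AFP is absent by design. Cirrhosis prevalence (2% healthy /
  30% HCC) and the stage I fraction (55%) are unpublished and are
  package defaults only — none of them enters an acceptance quantity.

The generator's `noise = "none"` mode replaces every stochastic count by
its mean and collapses the index onto the group median; the round trip
through `derive_index()` then returns the median exactly, which anchors
the normalization algebra.

## Diagnostics

* `normalize_score()` subtracts the mean control count (floored at 0);
  subtraction rather than division because background binding events add
  to a disc's counts. A ratio mode exists behind a flag since the
  published wording ("normalized to the negative control") is ambiguous.
* `ev_index()` divides by concentration / 10^9.
* `roc_curve()` uses thresholds at midpoints between consecutive unique
  values plus infinite sentinels, calls positive at `index >= t`, and
  integrates by trapezoid; this equals the Mann–Whitney statistic with
  half-credit for ties, which the tests verify to 1e-12.
  `youden_cutoff()` maximizes J = sensitivity + specificity − 1, ties
  toward the lowest cutoff (the screening-oriented choice; the published
  cutoff of 6 does not state its tie direction). `confusion_at()` calls
  positive at `index >= cutoff`.
* `two_proportion_ztest()` is the pooled z test (z² equals the
  uncorrected 2x2 Pearson chi-square; verified to 1e-10);
  `welch_ttest()` and `chi_square()` wrap the standard `stats`
  implementations (Welch–Satterthwaite; Pearson without Yates
  correction, matching the published convention of raw, uncorrected
  per-comparison p-values).
* `stratified_kfold()` shuffles within class and deals round-robin with
  a random rotation, so per-fold class counts deviate from exact
  proportionality by at most one (136 HCC over 5 folds gives
  {28,27,27,27,27}).
* `logistic_cv()` standardizes features on the training fold only
  (frozen parameters applied to the test fold), fits by IRLS with a
  1e-8 ridge jitter (max 100 iterations, 1e-8 coefficient tolerance) and
  flags quasi-separation when a standardized coefficient exceeds 15 or
  the iteration fails to converge; per-fold test AUC and accuracy at
  probability 0.5 are reported. The default feature set is the index
  alone; the published analysis does not state whether covariates
  entered the model, so covariates are available behind a flag.

## Numerical conventions and degenerate inputs

* All stochastic operations take an explicit seed and restore the
  caller's RNG state; identical config + seed gives byte-identical
  pipeline outputs.
* Channel intensities are quantized to the unsigned 16-bit range at
  render time (clipping is logged), so disk round trips are lossless.
* Degenerate paths are defined, not accidental: single-bin histograms
  raise errors; an empty annulus falls back to the global median;
  a pooled proportion of 0 or 1 gives z = 0, p = 1; zero variance in
  both Welch groups gives t = 0, p = 1 at equal means; zero background
  sd turns the positivity rule into "strictly positive".

## Problem sizes

The shipped tests and the acceptance script use three 512 x 512 fields
of ~269 spots per replicate (20 replicates, ~16,000 vesicles total) for
imaging recovery, and 100 replicates of the 186-subject cohort for index
recovery. These sizes hold the Monte-Carlo standard error of every
recovered fraction well below the tolerance asserted for it (for a
marginal fraction at n ≈ 807 per replicate, the seed-averaged standard
error is ≈ 0.3 percentage points) while keeping a full run on one CPU
core in the order of a minute.

## Known limitations

* Merged spots are counted once (no watershed splitting); the default
  minimum separation makes this rare in simulation, but dense real
  fields would bias counts downward.
* The triangle threshold assumes a dominant background mode with a
  one-sided signal tail; fields that are mostly foreground violate it.
* The positivity rule treats channels independently; no spectral
  unmixing is applied even when crosstalk is simulated.
* The cohort generator draws covariates independently of the index, so
  it cannot be used to study confounding without enabling the planted
  association knobs it deliberately lacks.
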