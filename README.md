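# sevtools

Analysis tools for **multiplex single-extracellular-vesicle (EV)
fluorescence imaging** and for the **CD98+ EV Index**, an EV-based
liquid-biopsy marker for early hepatocellular carcinoma (HCC). The
package is aimed at researchers who quantify surface-marker
co-expression on individual vesicles from multichannel microscope
fields, and who evaluate count-based EV biomarkers against clinical
groups.

Because neither raw images nor patient-level tables are publicly
available for this assay, both halves of the package pair the analysis
code with a synthetic-data generator whose defaults are planted at the
published operating points, so every pipeline stage is validated by
parameter recovery and by independent oracles.

## What it computes

**Imaging half.** A field is one total-stain channel (all vesicles)
plus three marker channels (CD63, CD9, CD98). Vesicles are detected in
the total-stain channel by a global *triangle threshold* (the histogram
bin maximizing the perpendicular distance to the peak-to-tail chord),
morphological opening + hole filling, 8-connected labeling and an area
gate. The resulting mask is applied unchanged to every marker channel;
per vesicle and channel a local-annulus median background is
subtracted, and marker *m* is called positive when

    corrected_mean_m > k_sigma * sigma_bg_m        (k_sigma = 3)

with `sigma_bg` the robust (MAD) background sd. The output is the
co-expression table: counts and fractions of the 8 marker combinations
over all detected vesicles, plus per-marker marginals.

**Diagnostics half.** Per subject, with sample well count *c*, same-disc
negative-control counts, and total EV concentration *C* (particles/mL):

    score = max(0, c - mean(controls))
    index = score / (C / 10^9)

The index is evaluated with ROC analysis (trapezoidal AUC, identical to
the Mann–Whitney statistic), the Youden cutoff
(max sensitivity + specificity − 1), confusion counts at a cutoff,
Welch *t* and two-proportion *z* tests, chi-square association tests,
and 5-fold stratified cross-validated logistic regression (IRLS,
fold-frozen standardization).

## Worked example

Simulate three 20x fields (~807 vesicles) with the default planted
combination frequencies, run the full imaging pipeline, and pool:

```r
library(sevtools)

meas <- lapply(1:3, function(i) {
  fld <- simulate_field(field_spec(), seed = 100 + i)
  measure_evs(fld, segment_field(fld))
})
coexpression_table(meas)
#> <coexpression_table> 800 detected EVs
#>                count fraction
#> CD63-CD9-CD98-   178    0.222
#> CD63+CD9-CD98-   297    0.371
#> CD63-CD9+CD98-     1    0.001
#> CD63+CD9+CD98-    61    0.076
#> CD63-CD9-CD98+     0    0.000
#> CD63+CD9-CD98+   102    0.128
#> CD63-CD9+CD98+     3    0.004
#> CD63+CD9+CD98+   158    0.198
#> marginals: CD63 77.3%  CD9 27.9%  CD98 32.9%
```

The planted population values were 77.7% CD63+, 26.9% CD9+, 33.0%
CD98+ with a 22.1% triple-negative class: the pipeline recovers each
marginal to within about one percentage point on a single three-field
replicate (the residual gap is multinomial sampling noise at n = 800
plus rare call errors at the 3-sigma threshold).

Simulate a 50 healthy / 136 HCC cohort from the published median/IQR
summaries (healthy 3.548 (3.821), HCC 9.761 (16.405)), derive the index
and evaluate it:

```r
cohort <- derive_index(simulate_cohort(cohort_spec(seed = 1)))
evaluate_diagnostics(cohort)
#> <ev_diagnostics>
#> <ev_roc> AUC = 0.753 (136 positive / 50 negative)
#>   cutoff 4.25 (Youden J = 0.424)
#> <confusion_counts> cutoff 4.25: TP 112 FP 20 TN 30 FN 24
#>   sensitivity 82.4%, specificity 60.0%
#> <test_result> Welch t: statistic = 7.334, df = 151.1, p = 1.264e-11 (two-sided)

logistic_cv(cohort$cd98_index, cohort$group, k = 5, seed = 1)
#> <ev_cv> 5-fold stratified CV (seed 1)
#>   AUC per fold: 0.744 0.748 0.868 0.693 0.733 (mean 0.757)
#>   accuracy per fold: 0.676 0.703 0.737 0.676 0.649 (mean 0.688)
```

An AUC around 0.75 is the expected operating point for two log-normal
groups with these medians and spreads; the exact Youden cutoff and
sensitivity/specificity split vary with the cohort draw.

A command-line wrapper covers the same pipeline
(`exec/sevtools run-all --seed 1 --out-dir out/`), with subcommands
`simulate-images`, `analyze-images`, `simulate-cohort` and `diagnose`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/field.R`, `R/field-io.R` | synthetic field generator, TIFF + sidecar I/O |
| `R/segmentation.R` | histogram, triangle threshold, morphology, labeling, area gate |
| `R/positivity.R`, `R/linescan.R` | mask transfer, background correction, positivity, co-expression, line scans |
| `R/cohort.R` | median/IQR log-normal fitting, cohort simulation, index derivation |
| `R/diagnostics.R`, `R/cv.R` | ROC/Youden/confusion, z/t/chi-square tests, stratified CV logistic regression |
| `R/pipeline.R` | config validation, pipeline orchestration, CLI |
| `vignettes/single-ev-analysis.Rmd` | models, parameter choices, limitations |
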