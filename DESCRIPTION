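Package: sevtools
Title: Single Extracellular-Vesicle Imaging Analysis and the CD98+ EV Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for multiplex single
    extracellular-vesicle (EV) fluorescence imaging and for an EV-based
    liquid-biopsy biomarker workflow. Includes a synthetic multichannel
    field generator with planted per-vesicle marker combinations, spot
    segmentation by global triangle thresholding with morphological
    cleanup and area gating, mask transfer with local background
    subtraction and per-marker positivity calling, co-expression
    tabulation, a synthetic patient-cohort generator driven by
    median/IQR summaries, and diagnostic evaluation of the CD98+ EV
    Index (control normalization, concentration normalization, ROC and
    Youden cutoff, two-proportion z tests, Welch t tests, chi-square
    tests, and stratified cross-validated logistic regression).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
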