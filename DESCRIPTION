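Package: dbsmetab
Title: Plate QC, Normalization and Matched-Pair Association for Targeted
    Dried Blood Spot Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control and analysis pipeline for targeted metabolomics
    of newborn dried blood spots measured on 96-well kit plates. Implements
    per-plate limit-of-detection estimation from paper blanks, LOD-based
    metabolite filtering, plate normalization against replicated QC2
    reference wells and metabolite target values, coefficient-of-variation
    filtering, rank-based inverse normal transformation, metabolome-wide
    matched case-control association with a pair-level random intercept,
    era-stratified scans, exact tests for diagnosis-code co-occurrence,
    and SNP-metabolite / SNP-ratio linear models. Ships a synthetic cohort
    and plate generator that emulates the matched-pair study design for
    power, calibration and regression testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
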