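Package: qmspanel
Title: Quantitative Methylation-Specific PCR Calibration, Cutoff
    Selection and Marker-Panel Evaluation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantitative fluorogenic
    methylation-specific PCR (QMSP) marker studies. Fits per-plate
    log-linear standard curves from serial dilutions of in vitro
    methylated DNA, converts threshold-cycle (Ct) values to input
    quantities, applies reference-gene (beta-actin) quality control and
    computes the gene/reference x 1000 relative methylation score.
    Selects empiric per-gene cutoffs on ROC curves by maximizing
    sensitivity plus specificity (Youden J), dichotomizes samples,
    cross-tabulates methylation status against clinical groups with a
    two-sided Fisher exact test (probability-mass rule, log-gamma
    arithmetic) or Pearson chi-square, and evaluates any-positive
    multi-marker panels against urine cytology (sensitivity,
    specificity, cytology-negative rescue). Includes a synthetic plate
    and cohort simulator with known ground truth, and the comparative
    CT (2^-ddCt) relative-expression method with a pooled-variance
    Student t-test for re-expression experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
biocViews: Epigenetics, DNAMethylation, qPCR, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
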