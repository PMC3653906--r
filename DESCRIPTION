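Package: urinpep
Title: Urinary CE-MS Peptidomics Processing and Multi-Peptide Classifier
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for urinary capillary-electrophoresis
    mass-spectrometry (CE-MS) peptidomics in chronic kidney disease (CKD)
    cohorts: peak-list filtering and charge-state deconvolution into
    neutral monoisotopic masses, migration-time calibration against a
    reference peptide panel by locally weighted regression, intensity
    normalization to housekeeping peptides, tolerance-based cross-sample
    peptide matching into a consensus intensity matrix, scoring of
    multi-peptide linear classifiers (CKD273-style) with a prognostic
    cutoff, and cohort statistics (MDRD eGFR, stage grouping, unbalanced
    one-way GLM, correlations, average-linkage patient clustering,
    per-peptide eGFR associations, monotone-peptide selection). Includes a
    synthetic cohort and peak-list generator with retained ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
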