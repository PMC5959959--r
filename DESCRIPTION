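Package: oascreen
Title: Targeted Urinary Organic Acid Quantification and Z-Score Screening
    for Inborn Errors of Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for targeted accurate-mass quantification
    of urinary organic acids from negative-mode LC-QTOF/MS full-scan data.
    Ships a 75-analyte biomarker panel (71 disease and 4 medication markers),
    extracts ion chromatograms at panel masses, integrates peaks, fits
    stable-isotope internal-standard calibration curves, normalizes
    concentrations to urine creatinine, and builds age-stratified log-scale
    reference statistics to render per-sample z-score profiles for screening
    of inborn errors of metabolism. Includes method cross-validation
    statistics (spiked recovery, linearity, Passing-Bablok regression,
    per-analyte significance testing) and a synthetic-data module that
    simulates control cohorts, patient cases, calibration batches and
    instrument-level peak lists so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
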