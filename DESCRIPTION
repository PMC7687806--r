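Package: sepsiscreen
Title: Sepsis Screening Scores from 15-Minute Critical Care Vital-Sign Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes SIRS (1992), qSOFA and SOFA positivity from
    high-frequency (15-minute) intermediate- and intensive-care vital-sign
    streams, cleans measurement artifacts with centered rolling-median
    filters, derives suspected-infection episodes from broad-spectrum
    antibiotic administration records (72-hour windows), and evaluates each
    score's discrimination of suspected infection and hospital mortality via
    two-point ROC analysis (sensitivity, specificity, AUC with Hanley-McNeil
    or bootstrap confidence intervals, paired DeLong comparisons). Ships a
    synthetic-cohort simulator with controllable infection prevalence,
    mortality and per-score operating characteristics so the full pipeline
    is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
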