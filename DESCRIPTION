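Package: pbmtox
Title: Pelvic Bone-Marrow Dosimetry and Haematologic Toxicity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing early haematologic toxicity after pelvic
    radiotherapy. Provides dose-volume histogram (DVH) handling and V-dose
    metrics for pelvic bone marrow and its substructures, the
    Lyman-Kutcher-Burman normal-tissue-complication-probability (NTCP) model
    with linear-quadratic fraction-size correction (EQD2) and multi-phase
    effective-dose summation, maximum-likelihood fitting of the LKB slope and
    position parameters with profile-likelihood confidence intervals, weekly
    blood-count processing with CTCAE v4.0 cytopenia grading, the standard
    group-comparison and regression battery with Holm and Benjamini-Hochberg
    multiple-testing control, and a calibrated synthetic cohort generator for
    conformal versus intensity-modulated delivery so the full pipeline can be
    exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
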