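Package: sperca
Title: Single-Cell Calcium Imaging and CatSper Electrophysiology Analysis
    for Human Sperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for agonist-evoked Ca2+ responses in human
    spermatozoa: ROI extraction and background correction of time-lapse
    fluorescence recordings, dF/F0 normalization, per-cell windowed responder
    classification, dose-response and amplitude-distribution summaries,
    pharmacological reversal quantification (CatSper blockers), whole-cell
    voltage-ramp current quantification, and viability/acrosome endpoint
    statistics. Ships a seeded synthetic-data generator calibrated to the
    recording protocols so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
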