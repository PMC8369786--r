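Package: ccar
Title: Cerebrospinal Fluid Cross-Section Area Ratio Analysis for Thoracic OLF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the cerebrospinal-fluid cross-section area ratio (CCAR)
    and related morphometric scores (OCAR, SCAR, mJOA recovery rate) from
    calibrated cross-sectional-area measurements in patients with thoracic
    ossification of the ligamentum flavum, classifies patients into
    diagnostic zones for dural ossification and neurological outcome, and
    provides the accompanying evaluation stack: empirical ROC curves with
    DeLong confidence intervals and Youden cut-off selection, diagnostic
    performance with exact Clopper-Pearson intervals, inter-observer
    intraclass correlation ICC(2,1), and group comparison tests. Includes a
    synthetic cohort generator and geometric phantom slices with analytically
    known areas so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
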