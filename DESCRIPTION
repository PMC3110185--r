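Package: escreen
Title: Embryonic Stem Cell Screen Simulation and Concentration-Response
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for plate-based two-channel In-Cell Western
    screens of embryonic stem cell cytotoxicity and cardiomyocyte
    differentiation. Provides a 96-well plate simulator with known
    ground-truth Hill responses, background correction and vehicle
    normalisation, control-band activity classification with
    four-parameter Hill AC50 estimation and AC_F derivation, assembly of
    chemical-by-assay potency matrices with Fisher exact and t-test
    association screening, pathway perturbation scores, a stepwise
    additive classifier tuned by cross-validated ROC AUC, and
    Table-1-style screen summaries with Ward/Euclidean heatmap ordering.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
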