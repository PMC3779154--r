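Package: qhtscreen
Title: Quantitative High-Throughput Screening Analysis for Primary-Cell
    Cytotoxicity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for quantitative high-throughput
    screening (qHTS) cell-viability assays in 1536-well format: plate-layout
    and concentration-series arithmetic, control-anchored normalization with
    spatial pattern correction from bracketing DMSO-only plates, Z'-factor
    and signal-to-background quality control, four-parameter logistic
    concentration-response fitting, concentration-response curve (CRC)
    classification, consensus hit calling across patient samples,
    tumor-versus-normal selectivity scoring, activity-profile clustering,
    and caspase-activation curve analysis with bell-shape masking. Includes
    a synthetic-screen generator with planted ground-truth pharmacology so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
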