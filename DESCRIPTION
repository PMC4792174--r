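Package: isoturn
Title: Protein Turnover Kinetics from Heavy-Water Metabolic Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo protein turnover measured by
    deuterated-water (2H2O) metabolic labeling and high-resolution mass
    spectrometry. Computes natural isotope envelopes and deuterium-accessible
    labeling sites from peptide sequences, calibrates body-water deuterium
    enrichment from GC-MS acetone-exchange measurements, fits a non-steady-state
    first-order kinetic model to 0th-isotopomer time series to obtain peptide
    turnover rate constants, applies stringency filters, rolls peptide rates up
    to protein-level medians, and quantifies relative protein abundance by
    normalized extracted-ion-chromatogram intensity and spectral counting
    (NSAF). Includes a synthetic-data generator that emulates the statistical
    structure of a multi-strain mouse labeling study so every stage of the
    pipeline can be exercised and validated without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
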