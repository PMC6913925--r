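Package: mpnenv
Title: Most-Probable-Number Quantification of Fecal Contamination in
    Environmental Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fecal indicator bacteria (E. coli) in
    environmental samples assayed with 97-well defined-substrate trays
    (Quanti-Tray 2000 / Colilert). Provides maximum-likelihood
    most-probable-number (MPN) estimation with profile-likelihood
    confidence intervals, censoring-aware aggregation of serial-dilution
    series, normalization to matrix-specific reporting units for ten
    environmental sample types (waters, soil, latrine swabs, produce,
    street food), neighborhood-level summary and comparison statistics on
    log10 concentrations, and a seeded synthetic-study generator that
    emulates a multi-neighborhood urban sampling design for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    foreign,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
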