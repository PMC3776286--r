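Package: dynwqi
Title: Water Quality Indices with Dynamic Weight Renormalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a drinking-water quality index (WQI) as a weighted sum of
    per-parameter quality values, with per-record dynamic weight renormalization
    so that samples with missing parameters remain usable. Ships the standard
    13-parameter drinking-water criteria set (weights and guideline limit
    values), a five-band quality classification, spreadsheet-style descriptive
    statistics, correlation-matrix principal component analysis with Kaiser
    retention and communality/uniqueness diagnostics, ordinary least squares of
    the index on component scores, a synthetic data generator with block
    correlation structure and random missingness, monitoring-report output, and
    a command-line interface.
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
    optparse,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
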