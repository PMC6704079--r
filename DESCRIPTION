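Package: prenylflux
Title: Quantitative Metabolomics and 13C Isotopologue Profiling of
    Isoprenoid Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for quantitative metabolomics and
    instationary 13C isotope labeling experiments (ILE) on the
    mevalonate/prenyl-pyrophosphate pathway: exact-mass calculation for
    targeted LC-HRMS acquisition, correction of measured mass fractions for
    natural isotope abundance and tracer purity, mean 13C-enrichment,
    logistic labeling kinetics with half-times (T50), absolute
    quantification by isotope dilution mass spectrometry (IDMS) with
    LOD/LOQ/linear-range validation, Welch comparisons between strains, and
    turnover-based relative flux inference. Ships a ground-truth-known
    simulator of instationary labeling dynamics, measurement noise,
    internal-standard signals and calibration series so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
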