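Package: nerveflux
Title: Extracellular Flux Analysis of Peripheral-Nerve Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy workflow for plate-based mitochondrial stress-test
    (Seahorse-style) respirometry of peripheral-nerve fragments: long-format
    plate import/export, per-well quality control for inhibitor response,
    group baseline adjustment, extraction of the classical mitostress
    parameters (non-mitochondrial, basal, ATP-linked, leak and maximal
    respiration, spare capacity, coupling efficiency), reference-line
    mitotoxicity indices (MTI-F, MTI-U, basal and FCCP z-scores),
    proteomics-based mitochondrial-enrichment-factor normalization,
    animal-level replicate pooling and group statistics, plus a synthetic
    plate simulator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
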