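Package: tcchart
Title: Tumor Content Chart-Assisted HER2/CEP17 Digital PCR Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates HER2/CEP17 copy-number ratios from chamber counts of
    a partitioned digital PCR array using the Poisson occupancy correction,
    combines the measured ratio with the tumor content ratio (the fraction
    of nucleated cells that are cancer cells) in a closed-form tumor/stroma
    mixture model, and classifies samples as HER2-amplified, equivocal, or
    non-amplified on a Tumor Content (TC) chart. Also provides dual-probe
    in situ hybridization (DISH) signal scoring with ASCO/CAP-style
    classification, nucleus-size-based tumor content estimation, a seeded
    chamber-count simulator for validation, and reporting and chart
    rendering utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ggplot2,
    scales,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
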