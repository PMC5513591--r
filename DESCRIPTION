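Package: d2oflow
Title: Milk Flow in Lactating Rodents from Deuterated-Water Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates maternal milk production in lactating rodents from
    deuterium oxide (D2O) dilution and turnover. A two-compartment
    (dam to litter) water-turnover model is fitted to baseline-corrected
    D2O enrichment time courses in dam plasma and pooled litter urine by
    weighted nonlinear least squares, yielding the dam-to-litter transfer
    constant, maternal total body water by isotope dilution, and milk flow
    with covariance-based uncertainty. Also provides the weight-suckle-weight
    comparator, exact (enumeration) Mann-Whitney and Welch t group
    comparisons, a synthetic-study generator with known ground truth, and
    CSV ingestion for complete two-experiment analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
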