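Package: ritfit
Title: Quantify Pod Shatter Resistance from Random Impact Test Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a two-parameter exponential decay to intact-pod counts
    from Random Impact Test (RIT) assays of Brassica fruit, extracts the
    RIT50 half-life with delta-method (error-propagation) confidence
    intervals, aggregates replicate assays per genotype, and compares
    mutant genotypes against a wild-type reference with significance
    stars and fold changes. Includes a stochastic RIT simulator
    (exponential pod break-times observed as interval counts) for
    oracle tests, confidence-interval calibration studies and
    end-to-end pipeline checks, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
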