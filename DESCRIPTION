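Package: evarena
Title: Evolutionary Arena Components and Phylogenetic Regression for
    Clade Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies, for clades delimited on a dated phylogeny by a
    stem-age time slice, the four components of the evolutionary-arena
    framework: net diversification rate (method-of-moments estimator with a
    relative extinction fraction), abiotic arena size (rarefied counts of
    suitable grid cells), within-clade competition (the product of Schoener's
    niche overlap and geographic range overlap, averaged per clade), and
    niche-evolution rate (summed per-trait Brownian-motion rates).  Joins the
    components with a phylogenetic generalized least squares regression
    reporting standardized slopes, likelihood-based R-squared and per-predictor
    partial r-squared.  Includes a synthetic-data generator (birth-death trees,
    multivariate Brownian traits, suitability grids with controllable overlap,
    responses with known effects) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
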