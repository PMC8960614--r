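Package: mrmediate
Title: Two-Step Mendelian Randomisation for Mediation with GWAS Summary
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-stage Mendelian randomisation pipeline over GWAS summary
    statistics: bidirectional univariate MR screening of candidate traits
    against a mediator (liability to type 2 diabetes) with Benjamini-Hochberg
    false-discovery-rate control, followed by multivariable MR and a two-step
    product-of-coefficients mediation decomposition separating the direct
    effects of traits on atherosclerotic cardiovascular outcomes from the
    effects mediated by the mediator. Includes instrument selection, greedy
    LD clumping against a supplied correlation matrix, allele harmonisation
    with frequency-based resolution of palindromic variants, inverse-variance
    weighted, MR-Egger, weighted-median and mode-based estimators with
    heterogeneity and instrument-strength diagnostics, and a seeded generator
    of three-sample summary statistics with known causal structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
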