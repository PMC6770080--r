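Package: ivwMR
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a two-sample Mendelian randomization pipeline for
    GWAS summary statistics: instrument selection at a genome-wide
    significance threshold, allele harmonization across exposure and
    outcome studies (including frequency-based resolution of palindromic
    variants), per-variant Wald ratio estimates with delta-method standard
    errors, fixed- and random-effects (DerSimonian-Laird) inverse-variance
    weighted pooling with Cochran's Q / I-squared heterogeneity statistics
    and heterogeneity-test-driven model selection, first-stage F-statistics
    for instrument strength, and instrument-exclusion sensitivity analyses
    (leave-one-out and named exclusion sets). A seeded generator of
    synthetic two-sample summary statistics, modelled on a three-variant
    serum vitamin E instrument applied to coronary artery disease
    case-control data, supports end-to-end testing and Monte Carlo
    calibration without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
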