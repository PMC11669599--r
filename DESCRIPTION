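Package: medmr
Title: Two-Sample and Two-Step Mediation Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics and for two-step mediation MR that decomposes an
    exposure-outcome total effect into direct and mediator-carried parts.
    Includes instrument selection (p-value thresholding, greedy LD clumping,
    F-statistic filtering), allele harmonization with palindromic-variant
    removal, five causal estimators (inverse-variance weighted, MR-Egger,
    weighted median, weighted and simple mode), a sensitivity battery
    (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out, Bonferroni
    classification), product-of-coefficients mediation with delta-method
    confidence intervals, reverse-MR guards, and a seeded synthetic
    summary-statistics generator with known causal structure for testing
    the full pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
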