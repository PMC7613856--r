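Package: ridgescreen
Title: Two-Stage Ridge Screening for Biomarker-Treatment Interactions
Version: 1.0.0
Authors@R:
    person("J.", "Kimball", email = "jkimball@example.org",
           role = c("aut", "cre"))
Description: Detection of biomarker-treatment interactions in randomized
    clinical trials with high-dimensional, possibly correlated biomarker
    panels. Implements two-stage testing: a first-stage marginal screen
    (one-biomarker-at-a-time association tests, or a multivariate ridge
    regression that adjusts every biomarker for all others and for the
    treatment main effect), followed by second-stage one-at-a-time
    interaction Wald tests whose significance thresholds are allocated by
    Bonferroni, subset-Bonferroni, or a rank-weighted bucket scheme.
    Includes a block-correlated randomized-trial simulator, closed-form
    proportion-of-variance-explained calculations, Monte-Carlo estimation
    of cluster-discovery power and familywise error rate, a between-stage
    independence diagnostic, preprocessing for real trial tables
    (missingness filtering, mean imputation, top-variance probe selection),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
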