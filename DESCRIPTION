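Package: dyadsynch
Title: Dyadic Synchrony and the Social Transmission of Nocebo Hyperalgesia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dyadic psychophysiology experiments on the
    social transmission of nocebo hyperalgesia along demonstrator-observer
    chains. Provides phasic electrodermal (peak-to-peak) and facial
    action-unit pain-expression scoring, from-scratch cross-recurrence
    quantification (recurrence rate, determinism, laminarity) with automatic
    parameter selection targeting a 2-4% recurrence rate, trial-level
    psychological synchrony, Monte-Carlo permutation responder
    classification, mixed ANCOVA with adjusted marginal means and partial
    eta-squared intervals, hierarchical moderation regressions with simple
    slopes, and a synthetic transmission-chain generator so the full
    pipeline runs and is testable without the original recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    signal,
    car,
    yaml,
    jsonlite,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
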