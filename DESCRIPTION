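Package: gaitsyn
Title: Muscle Synergies and Local Dynamic Stability of Treadmill Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for normal and narrow-base treadmill walking
    studies: surface-EMG envelope preprocessing and stride-time normalization,
    muscle synergy extraction by non-negative matrix factorization with
    Lee-Seung multiplicative updates (fixed muscle weightings across
    conditions and time-points), activation-timing metrics (full width at
    half maximum, center of activity), gait event detection from the center
    of pressure, spatiotemporal and trunk center-of-mass outcome measures,
    the local divergence exponent of trunk motion by Rosenstein's algorithm,
    and a repeated-measures plus circular (Harrison-Kanji) statistical layer.
    Includes a synthetic-data generator with known ground truth (synergy
    weightings, activation profiles, gait events, foot placements, stride-to-
    stride divergence) so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    data.table,
    zoo,
    deSolve,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr
Config/testthat/edition: 3
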