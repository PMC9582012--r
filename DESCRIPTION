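Package: fearnet
Title: Functional Networks and Encoding Models for Probabilistic Fear
    Discrimination Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for single-unit recordings collected during
    probabilistic fear discrimination, in which auditory cues predict foot
    shock with probability 1.00 (danger), 0.25 (uncertainty) or 0.00
    (safety). Provides conditioned-suppression behavior metrics, peri-event
    binning and baseline normalization of spike trains, k-means functional
    clustering of condition firing profiles, population PCA with a
    shuffle-based per-cluster variance attribution statistic, correlation
    defined functional networks with hub scoring, per-unit trial-wise
    encoding regressions contrasting threat probability against fear
    behavior (cue period) and sensory shock against prediction error
    (outcome period), and in-silico network "lesion" re-analysis. Includes
    an inhomogeneous-Poisson synthetic session generator with known
    ground-truth coding structure so every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
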