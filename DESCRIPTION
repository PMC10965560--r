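Package: emorec
Title: Real-Time EEG Emotion Recognition via Band Power, Channel Selection
    and Valence-Arousal-Dominance Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising discrete emotions from
    multichannel EEG. Trials are segmented into overlapping windows, power
    spectral densities are integrated over the five canonical bands (delta,
    theta, alpha, beta, gamma) together with four band-ratio indices; an
    eight-channel montage is selected by combining lobe-wise PCA first
    components, mean absolute Pearson correlation with continuous
    valence/arousal/dominance ratings, and random-forest Gini importances
    aggregated into an Emotion Importance Index; three 3-class classifiers
    (one per rating axis) are compared across five model families under
    shift-based cross-validation; and a buffered streaming loop emits a
    discrete VAD triple and its mapped emotion (including Descartes' six
    passions) every five seconds. A synthetic-data generator emulating
    DEAP-shaped recordings with planted band-power/rating couplings makes
    every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    xgboost,
    e1071,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
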