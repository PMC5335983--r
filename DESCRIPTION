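Package: BeatRank
Title: Set-Based Discriminative Measure for ECG Beat Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies electrocardiogram (ECG) beats by ranking corpus
    sets against query sets with a set-to-set dissimilarity measured in a
    learned Mahalanobis metric space. Beats are encoded by multi-level
    discrete wavelet decomposition (sub-band statistics or full
    coefficients), the metric is learned by a structural ranking
    objective with truncated reciprocal-rank loss optimised by a
    cutting-plane algorithm, and class assignment uses the
    Minority-Based Dissimilarity together with the classic minimum
    point-wise, mean approach, and average point-wise set distances.
    Includes a synthetic beat and feature-cluster generator, readers for
    WFDB-format records and delimited beat tables, and an evaluation
    harness with repeated stratified splits, per-class training caps and
    Rank-1/Rank-5 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'BeatRank-package.R'
    'accessors.R'
    'utils.R'
    'beats-io.R'
    'wavelet-filters.R'
    'wavelet-features.R'
    'mlr-solver.R'
    'mlr-metric.R'
    'set-dissimilarity.R'
    'evaluation.R'
    'synthetic-beats.R'
    'synthetic-clusters.R'
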