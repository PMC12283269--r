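Package: pascl
Title: Photoacoustic Spectral Analysis with Supervised Contrastive Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-wavelength photoacoustic power-spectrum analysis
    and tissue classification. Provides a synthetic cohort generator with
    class-dependent spectral slope and band offsets, per-patient random
    effects and per-system calibration gains; Welch power-spectral-density
    preprocessing with band selection, calibration and linear-fit features
    (slope, intercept, median); a small convolutional network trained with
    cross-entropy, two-stage supervised-contrastive, or combined
    supervised-contrastive plus cross-entropy losses; patient-grouped
    splitting and seeded stochastic gradient descent training with random
    hyperparameter search; a five-metric evaluation protocol with subsampled
    test sets and Welch t-tests; noise-injection robustness and cross-system
    transfer benchmarks; and classical baselines (feature thresholds,
    regularised linear and quadratic discriminants, validation-driven
    feature screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    cluster,
    signal,
    jsonlite,
    yaml,
    data.table,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
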