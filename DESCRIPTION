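Package: RamanPhase
Title: Raman Spectral Chemometrics for Classifying Hypoxic-Ischemic
    Physiological Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying basal, hypoxic-ischemic and
    post-hypoxic-ischemic physiological states from in vivo Raman spectra.
    Provides a synthetic-study generator emulating a piglet asphyxia
    experiment (phase timelines, blood-gas trajectories, pseudo-Voigt band
    models with fluorescence baseline and scatter artifacts), a spectral
    preprocessing chain (trimming, extended multiplicative signal
    correction, asymmetric least squares baseline removal, Savitzky-Golay
    smoothing, PCA-based outlier rejection via Q residuals and Hotelling's
    T2), NIPALS partial least squares discriminant analysis and hybrid
    PLS-plus-classifier models in a two-component latent plane,
    leave-one-subject-out cross-validation with confusion-matrix figures of
    merit, permutation feature importance over wavenumbers, subject-averaged
    learning curves, and a univariate blood-gas benchmark (Mann-Whitney U
    with rank-biserial effect size, Spearman correlation, clinical pH and
    lactate cut-off classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
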