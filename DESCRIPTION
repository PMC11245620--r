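Package: ccapower
Title: Stability, Power and Sample-Size Analysis for CCA and PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative modeling framework for studying the stability of
    canonical correlation analysis (CCA) and partial least squares (PLS-SVD).
    Constructs joint covariance models with power-law within-set variance
    spectra and a planted rank-1 between-set association of known strength,
    simulates multivariate normal datasets from them, and quantifies
    statistical power and estimation errors (association strength, weights,
    scores, loadings) of CCA/PLS solutions as a function of sample size.
    Provides seeded parameter sweeps, spline-interpolated required sample
    sizes under a combined five-metric criterion, a log-linear sample-size
    calculator, retrospective weight-error estimation for reported CCA
    results, and an empirical-data preparation pipeline (deconfounding,
    rank-based inverse normal transform, PCA reduction, nearest positive
    definite covariance, subsampled stability audits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
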