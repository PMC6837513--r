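Package: speccal
Title: Calibration Design for Hyperspectral Prediction of Grain Nutrients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and evaluating calibration models that link
    near-infrared hyperspectral image spectra of cereal grains to nutrient
    concentrations measured by wet chemistry. Covers the full workflow:
    reflectance correction of raw spectral cubes against dark-current and
    white-reference measurements, grain/background segmentation by Neural Gas
    clustering with a radial-basis-function pixel classifier, per-sample
    spectrum averaging, spectrum-to-trait regression (NIPALS partial least
    squares, RBF network and multi-layer perceptron back-ends),
    resampling-based evaluation of calibration set sizes and multi-environment
    compositions, model transferability matrices, cost-benefit and logarithmic
    learning-curve analysis, and the supporting statistics (variance components
    and repeatability, coefficients of variation, Fisher-z model comparison
    with Tukey letters, Fligner-Killeen variance homogeneity). Includes a
    synthetic data generator emulating a multi-environment barley field trial
    so the whole pipeline is testable without proprietary image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
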