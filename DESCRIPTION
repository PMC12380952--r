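Package: levyflight
Title: Levy-Flight Decision Model Simulation, Estimation and Reliability
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of the Levy-flight decision model (an
    evidence accumulator driven by symmetric alpha-stable noise, with the
    diffusion decision model as its Gaussian special case), likelihood-free
    per-participant parameter estimation with calibration and recovery
    harnesses, and the reliability machinery needed to study whether the
    stability index measures a stable individual trait: test-retest and
    across-task correlation with Mahalanobis screening, Kraskov k-NN mutual
    information and conditional-MI retention, gradient-boosted
    intrinsic-reliability analysis, practice-effect tests, and regression
    presets relating the stability index to behavioral measures. Includes a
    synthetic two-session study generator with known ground truth so the
    whole pipeline runs without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    jsonlite,
    pracma,
    e1071,
    xgboost,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
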