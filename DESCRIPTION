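Package: adaptloo
Title: Adaptive Importance Sampling for Bayesian Leave-One-Out Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximate leave-one-out (LOO) cross-validation for Bayesian
    classification models from posterior draws, without refitting. Raw 1/likelihood
    importance weights are stabilized by Pareto smoothing; observations whose
    Pareto tail-shape diagnostic exceeds a threshold are rescued by perturbative
    bijective transformations of the draws (partial moment matching and single
    gradient-flow steps descending the KL divergence to the LOO target or the
    variance of the importance sampler), with exact or first-order Jacobian
    determinant corrections. Closed-form Jacobians are provided for logistic
    regression and one-hidden-layer ReLU networks. Includes a synthetic n << p
    generator, lightweight posterior samplers, and brute-force refit oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
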