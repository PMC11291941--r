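Package: cogreserve
Title: Machine-Learning Surrogates for Residual-Based Cognitive Reserve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating clinical-feature surrogates of a
    residual-based cognitive reserve criterion. The package generates synthetic
    cognitive-ageing cohorts with known latent reserve structure, estimates the
    residual reserve index from a single-indicator linear-Gaussian latent model
    of episodic memory, trains tiered gradient-boosted surrogates of the
    criterion with cross-validated Bayesian-style hyperparameter search,
    validates surrogates through nested longitudinal mixed-model moderation
    ladders compared by likelihood-ratio tests, and attributes predictions to
    features via Shapley values and split-gain importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    xgboost,
    lhs,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
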