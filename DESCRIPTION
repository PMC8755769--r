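Package: tracecf
Title: Calibration-Driven Counterfactual Explanations for Image Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncertainty-aware counterfactual explanations for deep image
    classifiers and regressors. Trains a Wasserstein autoencoder to obtain a
    low-dimensional continuous latent space, fits an interval-calibrated
    predictor pair (point estimates plus prediction-interval half-widths) by
    alternating interval-calibration and hinge objectives, and optimizes
    counterfactual latent codes under a calibration-driven objective together
    with vanilla, mixup, Monte Carlo dropout, deep-ensemble and
    uncertainty-weighted confidence-calibration baselines. Includes the
    standard counterfactual evaluation metrics (validity, confidence,
    sparsity, proximity, realism), shortcut-detection and attribute-fusion
    analyses, and a synthetic radiograph-like image generator so the whole
    pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
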