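Package: ovaUQ
Title: Uncertainty-Aware Evaluation of One-vs-All Multi-Class Classifiers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies predictive uncertainty of multi-class classifiers via
    One-vs-All decomposition. Provides reference stochastic predictors (a
    dropout feed-forward network with Monte Carlo dropout inference, deep
    ensembles, ensemble Monte Carlo dropout, and a mean-field Gaussian
    Bayesian weight sampler), predictive-mean and predictive-entropy
    summaries, certainty thresholding, the uncertainty confusion matrix and
    its metrics (UAcc, USen, USpe, UPre, UF1), calibration metrics (expected
    calibration error, Brier score), AUC-ROC, and percentage-uncertainty
    comparisons between traditional and uncertainty-aware metrics. Includes a
    synthetic class-conditional Gaussian data generator with controllable
    inter-class overlap, a class-rebalancing One-vs-All evaluation pipeline,
    and delimited-table report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'metrics.R'
    'net.R'
    'bayes.R'
    'samplers.R'
    'synthetic.R'
    'pipeline.R'
    'report.R'
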