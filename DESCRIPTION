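Package: dtsdroc
Title: Dual-Trace Signal Detection Modeling of Confidence-Rating ROC Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling abnormality-detection performance from
    confidence-rating data with a dual-trace signal detection (DTSD) model,
    a mixture of a continuous equal-variance signal detection component
    (global d') and a discrete high-threshold component (local HT).
    Provides closed-form ROC predictions, binning of fine-grained rating
    scales into empirical ROC curves, a synthetic-data generator with
    group-by-condition parameter structure, hierarchical Bayesian (JAGS)
    and per-subject maximum-likelihood fitting, scripted parameter-recovery
    experiments, and a destination-vector analysis of mouse-cursor
    trajectories recorded on an arc-shaped confidence scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
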