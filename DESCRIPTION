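Package: symptraj
Title: Latent-Class Trajectories of Depressive Symptoms and Their
    Immunometabolic Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling developmental trajectories of repeated
    depressive-symptom scores (13-item Short Mood and Feelings
    Questionnaire, ages 10-25) with latent-class trajectory models
    (group-based trajectory models and growth mixture models on
    fractional-polynomial bases), a multi-step model-selection framework
    (BIC, integrated completed likelihood, relative entropy, average
    posterior probability and odds of correct classification gates), and
    downstream association of assigned classes with clinical outcomes via
    modified-Poisson risk-ratio regression and with high-dimensional
    blood biomarker panels via empirical-Bayes moderated linear models
    with false-discovery-rate control. Includes a synthetic-cohort
    generator emulating the longitudinal study design (occasion-level
    missingness, below-detection-limit censoring, planted class effects)
    so the full pipeline is testable without managed-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich,
    rlang
Suggests:
    testthat (>= 3.0.0),
    limma,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
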