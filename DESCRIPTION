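Package: neogastric
Title: Population Pharmacodynamic Modelling of Neoadjuvant Therapy in
    Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-effects ordered-categorical modelling of tumour response
    to neoadjuvant therapy in locally advanced gastric and
    gastroesophageal-junction cancer, with first-order Markov dependence
    between scheduled assessments, together with parametric time-to-event
    models for metastasis appearance and overall survival carrying covariates
    on the baseline hazard and a time-dependent metastasis effect. Includes
    Laplace, adaptive Gauss-Hermite and Monte Carlo marginal likelihoods,
    likelihood-ratio covariate screening, visual predictive checks,
    nonparametric bootstrap, descriptive staging-concordance analyses, and a
    synthetic-cohort generator emulating the 115-patient study design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    survival,
    mvtnorm,
    pracma,
    MASS,
    yaml,
    readxl
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
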