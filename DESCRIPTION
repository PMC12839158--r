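Package: faindex
Title: Plasma Fatty-Acid Indices and Diagnostic Modelling for Atherosclerosis
Version: 0.1.0
Authors@R:
    person("faindex", "maintainers", email = "faindex@example.org", role = c("aut", "cre"))
Description: Tools for plasma fatty-acid lipidomics: conversion of per-analyte
    concentrations (ng/mL) to molar-percent composition, conventional and
    composite polyunsaturated fatty-acid indices (Omega-3 Status, omega-6/3
    ratio, AA/EPA, pathway ratios, and the Omega-6/3 Balance Index), ROC
    analysis with DeLong variance and Youden mid-plateau cut-offs, Cliff's
    delta effect sizes, a group-comparison decision tree with Holm and
    Benjamini-Hochberg adjustment, LASSO-based logistic model development
    with bootstrap optimism-corrected internal validation, a published
    two-predictor diagnostic logit function, and a moment-calibrated
    synthetic cohort generator so the whole pipeline runs without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
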