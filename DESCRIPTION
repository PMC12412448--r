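Package: feedbackmpt
Title: Multinomial Processing Tree Analysis of Memory for Veracity Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recognition-memory experiments in which
    statements are studied together with veracity feedback ("true", "false",
    or "?") and later tested for both item recognition and feedback
    attribution. Implements the three-source variant of the two-high-threshold
    source-monitoring model as a multinomial processing tree (MPT) model,
    maximum-likelihood fitting of aggregated category frequencies with
    likelihood-ratio (G-squared) goodness-of-fit tests, nested-model
    comparisons of parameter constraints, an order-constrained shrinkage
    reparametrisation of the feedback-memory parameters, trial-level
    behavioral measures (CSIM, SIM, discrimination index Pr) with
    repeated-measures ANOVA, a synthetic-data generator emulating the
    plausibility-by-feedback study design, and simulation-based and analytic
    power analysis. EQN model files are read and written for interchange with
    standard MPT tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
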