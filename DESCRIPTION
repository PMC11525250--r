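Package: iedrl
Title: Attention-Modulated Reinforcement Learning Models of Intra-Extra
    Dimensional Set Shifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulator and trial-by-trial choice models for the
    nine-stage CANTAB intra-extra dimensional (IED) set-shift task, together
    with hierarchical expectation-maximisation parameter estimation, integrated
    BIC model comparison, parameter-recovery and posterior-predictive
    validation, error-trajectory clustering, and permutation-based
    symptom-association statistics. Includes a synthetic-cohort generator with
    planted parameter-questionnaire correlations so the full analysis pipeline
    can be exercised without access to proprietary task data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
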