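Package: asymrpe
Title: Asymmetric Reward Prediction Error Coding in Intracranial High-Frequency Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying asymmetric coding of
    reward prediction errors (RPEs) in intracranial high-frequency activity (HFA).
    Includes an adaptive-staircase interval-timing task simulator with ideal-observer
    agents, trial-level derivation of expected value and signed/unsigned/valence-split
    RPEs from a tolerance-logistic value model, a hierarchical linear mixed-model
    ladder for reaction-time adaptation, a synthetic iEEG cohort generator with
    ground-truth channel coding categories and lag-coupled channel pairs, multitaper
    HFA power extraction with bootstrap baseline normalization, window-wise
    encoding-model comparison with channel responsiveness classification, and
    time-lagged cross-correlation estimates of directed connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    nnet,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
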