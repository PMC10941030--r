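Package: soleplay
Title: Game-Based Screening of Peripheral Neuropathy and Cognitive
    Dysfunction from Plantar-Pressure Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for serious-games screening of
    peripheral neuropathy (PNP) and cognitive dysfunction (CD) in elderly
    diabetes cohorts. Provides a configurable catalogue of four
    pressure-controlled video games played through sensor-equipped insoles,
    a synthetic cohort generator with clinically consistent NDS/NSS/MoCA
    scores, a per-task session simulator driven by latent impairment traits,
    primary and task-combination feature extraction, normality-gated cohort
    statistics with Holm-Bonferroni correction, cardinality matching with
    covariate-balance constraints, logistic odds-ratio association models,
    and a correlation-pruned, top-k feature-selected, repeated
    cross-validated classification comparison of individual-risk-profile
    versus profile-plus-game models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
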