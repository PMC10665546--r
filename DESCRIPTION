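Package: panelhmm
Title: Multilevel Hidden Markov Models for Weekly Ordinal Symptom Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intraindividual phenotyping of longitudinal ordinal
    symptom panels with multilevel Bayesian hidden Markov models. Provides a
    synthetic cohort generator that mirrors a weekly symptom-interview study
    design, exact forward/backward/Viterbi machinery for multivariate
    categorical emissions with missing data, MCMC estimation of group-level
    and subject-level transition and emission parameters on the
    multinomial-logit scale, AIC-based selection of the number of latent
    states, per-subject Markov dynamics (inertia, stationary occupancy, mean
    first-passage and recurrence times), and post hoc association analyses
    linking dynamics to demographic covariates and comorbid symptom severity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    nlme,
    readr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
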