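Package: nfdrift
Title: Spontaneous EEG Band-Power Dynamics in Neurofeedback-Like Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of trial-structured EEG band
    power in passive, neurofeedback-like visual tasks. Generates synthetic
    multi-subject EEG cohorts with controllable ground-truth effects (a
    per-trial alpha drift, a condition-level theta increment, and optional
    steady-state visual responses), applies zero-phase IIR preprocessing and
    Welch band-power extraction, builds planned condition contrasts by
    generalized inverse of a hypothesis matrix, fits Bayesian linear
    multilevel models with maximal varying effects via Gibbs sampling (JAGS),
    quantifies evidence with Savage-Dickey Bayes factors (including a
    five-repeat stability protocol and prior-sensitivity sweeps), and
    generates sham feedback stimulus trajectories from band-power variation
    series with surrogate temporal-statistics validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    rjags,
    coda,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
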