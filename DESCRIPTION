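Package: kalmanbandit
Title: Kalman-Filter Bandit Learning Models and Estimation-Uncertainty Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and model-based analysis of two-armed bandit
    reinforcement-learning experiments with a learning phase (partial
    feedback) and a feedback-free test phase. Implements six learning
    models (constant-rate and dual-rate Q-learning, selected/rejected
    updating, contextual centering, range normalization, and a
    Kalman-filter learner with per-option estimation-uncertainty),
    two softmax decision models (value only, or value plus uncertainty),
    subject-level MAP fitting with Laplace model evidence, random-effects
    Bayesian model selection with protected exceedance probabilities,
    model- and parameter-recovery harnesses, and model-agnostic
    sampling-rate statistics including permutation tests for differences
    between correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
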