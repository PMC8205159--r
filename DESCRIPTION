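Package: surnor
Title: Surprise-Novelty-Reward Reinforcement Learning Models of Sequential
    Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and statistical analysis of goal-directed sequential
    decision-making in a deterministic maze-like task with an unannounced
    mid-experiment state swap. Implements a family of tabular reinforcement
    learning agents combining count-based novelty seeking, Bayes-Factor
    surprise, surprise-modulated model-free learning with eligibility traces,
    and a hybrid model-based/model-free policy; likelihood-based parameter
    fitting by coordinate ascent, cross-validated model evidence,
    random-effects Bayesian model selection with protected exceedance
    probabilities, parameter and model recovery analyses, behavioral
    summaries (escape latency, progress scores), and trial-by-trial
    model-based regression of event-related potentials with a synthetic ERP
    generator.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
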