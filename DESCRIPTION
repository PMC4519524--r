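Package: twostepRL
Title: Simulation and Model-Based Analysis of the Two-Step Sequential Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the balance between model-based and model-free
    reinforcement learning in the two-step sequential decision task, in both
    reward and punishment (monetary loss) valences. Provides a generative task
    engine with drifting outcome probabilities, hybrid SARSA/model-based agent
    simulation, the stay-probability factorial analysis with mixed-design
    ANOVAs, per-subject maximum-likelihood fitting of Q-SARSA and hybrid
    models, group-level random-effects Bayesian model selection over
    log-evidence, between-group parameter comparison (MANOVA), and end-to-end
    parameter- and model-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
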