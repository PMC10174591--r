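Package: fearvol
Title: Fear-Biased Adaptation to Volatility in Probabilistic Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and computational-modeling toolkit for cue-biased
    probabilistic reversal-learning tasks that cross an emotional cue
    (fearful vs neutral) with environmental volatility (frequent vs
    infrequent contingency reversals). Provides the task environment
    (reversal schedules, outcome delivery), a family of twelve
    Rescorla-Wagner-type learning models with condition-specific parameter
    sharing (lapse, forgetting, Pearce-Hall hybrid and linear-link
    variants), per-subject maximum a posteriori and hierarchical Bayesian
    fitting with WAIC and PSIS-LOO model comparison, a grid-based Bayesian
    observer that tracks trial-wise subjective volatility, model and
    parameter recovery diagnostics, and permutation statistics for the
    learning-rate bias index that quantifies how fear suppresses
    adaptation to volatility.
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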