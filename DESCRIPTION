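Package: seqinfer
Title: Sequential Inference Modelling for Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling choice behaviour on probabilistic reversal
    tasks with hidden Markov belief-updating models. Implements pure Bayesian
    filtering and fixed-window sequential inference over short sequences of
    hidden states (orders one to five), delta-rule action-value baselines,
    maximum a posteriori fitting with a fixed-precision two-pass procedure,
    BIC-based and random-effects Bayesian group model comparison with
    exceedance probabilities, Bayesian parameter averaging, per-subject
    sequential-inference measures, and a closed-loop task simulator for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
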