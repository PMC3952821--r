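Package: mphmm
Title: Mixed Pair Hidden Markov Models for Neural Stimulus-Response Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint generative modelling of a continuous stimulus sequence and
    a binned spike response as a mixed pair hidden Markov model (MPH).
    Matching (M) states emit stimulus-response pairs, while X and R states
    emit only a stimulus or only a response symbol, letting the model absorb
    variable response latencies and spike-time jitter; multiple M states
    capture switching receptive fields.  Provides banded dynamic-programming
    inference (generalized Viterbi, forward, backward, state posteriors and
    alignment kernels), EM parameter estimation under constraint flags,
    spike-probability prediction via an inference-equivalent model rewriting,
    an estimated output nonlinearity (cascade), the closed-form bridge to
    linear-nonlinear-Poisson (LNP) cascade models, and simulators and
    reference estimators (LNP spiking, discretized log-normal jitter,
    Markov-switching responses, STA, reverse correlation, STC) for end-to-end
    synthetic experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
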