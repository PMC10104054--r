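Package: beliefrnn
Title: Belief States and Value RNNs for Partially Observable Pavlovian Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulators for partially observable Pavlovian trace-conditioning
    tasks (probabilistic reward timing with and without omissions, and hidden
    reward-magnitude blocks), Bayesian belief-state filtering over the
    micro-state Markov formulation of those tasks, least-squares temporal
    difference (LSTD) value estimation and reward prediction errors, gated
    recurrent unit (GRU) value networks trained end-to-end by semi-gradient TD
    learning, echo state network (ESN) variants with frozen gain-scaled
    orthogonal reservoirs, and a suite of probes that quantify how belief-like
    a learned representation is: held-out linear belief regression R-squared,
    hidden-state decodability, principal component structure, fixed-point
    dynamics, and observation-memory durations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
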