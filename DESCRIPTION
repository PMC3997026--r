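Package: semlatch
Title: Latching Attractor-Network Simulation of Semantic Priming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates semantic priming as latching dynamics in coupled sparse
    Hopfield attractor networks. A semantic layer with synaptic depression and
    temporally correlated noise hops stochastically between correlated concept
    patterns; a lexical layer converges on word patterns under bottom-up visual
    input and top-down semantic feedback, and the lexical convergence time is
    the simulated reaction time. Includes exact-overlap sparse pattern
    generation, an optional orthographic relay layer for frequency and
    stimulus-degradation effects, episodic inter-pattern links, a
    reinforcement-learning controller of the two-component noise amplitude, an
    expectancy (feedback-gain) policy, a priming-experiment harness
    (SOA, relatedness proportion, mediated and backward conditions, free
    association), and analysis utilities with embedded human reaction-time
    reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
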