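Package: stdpmotifs
Title: Motif Expansion of STDP Drift and Self-Organization in Linear Poisson
    Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how spike-timing-dependent plasticity (STDP)
    shapes recurrent network connectivity. Implements the exact synaptic drift
    for networks of linear Poisson (Hawkes-type) spiking neurons, its expansion
    as a sum over structural motifs with coefficients computed from the STDP
    window and the synaptic current kernel, a stochastic spiking simulator with
    explicit pair-based STDP accumulation, the full plasticity dynamics
    (STDP, heterosynaptic competition, self-depression, constant growth, hard
    bounds, balanced inhibition), and a clustering-based score quantifying
    similarity of a connectivity matrix to a wide synfire chain or to
    self-connected assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
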