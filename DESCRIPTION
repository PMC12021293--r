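Package: metaplast
Title: Meta-Learning Synaptic Plasticity Rules in Recurrent Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers synaptic plasticity rules in recurrent
    excitatory/inhibitory conductance-based spiking networks by meta-learning.
    An inner loop simulates leaky integrate-and-fire networks (two variants,
    with and without adaptive thresholds and NMDA-like conductances) whose
    synapses evolve under parameterized spike-triggered plasticity rules; an
    outer Covariance Matrix Adaptation Evolution Strategy (CMA-ES) optimizes
    the rule parameters against network-level objectives such as firing-rate
    homeostasis and familiarity detection. Three rule parameterizations of
    increasing expressivity are provided (a six-parameter pair-based STDP
    polynomial, a 21-parameter separable polynomial with voltage and
    codependent-current factors, and a partially frozen multilayer perceptron),
    together with mean-field fixed-point predictions for validation,
    pre/post pairing-protocol visualization, and reproducible experiment
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
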