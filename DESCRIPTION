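Package: spikeintent
Title: Brain-Inspired Intention Prediction with Spiking Neurons and Reward-Gated STDP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a brain-inspired intention
    prediction model: populations of Izhikevich spiking neurons wired through a
    dorsolateral prefrontal cortex / basal ganglia / thalamus / motor cortex
    circuit, with reward routed through orbitofrontal pathways that gate
    spike-timing-dependent plasticity (STDP) on the single plastic projection.
    The network learns bijective state-to-intention rule sets from binary
    right/wrong feedback, relearns after rule changes without disturbing
    unchanged rules, and is compared against a tabular Q-learning baseline via
    exhaustive and sampled rule-space training-cost statistics. Includes a
    20-feature skeletal gesture encoder with an online correlation-based STDP
    classifier and synthetic data generators for gestures and trajectory
    states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
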