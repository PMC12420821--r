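Package: snndelays
Title: Exact Event-Based Co-Training of Weights and Delays in Spiking
    Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-based simulation and training of feed-forward spiking
    neural networks whose forward and backward passes operate purely on
    spike times. First-spike times of leaky integrate-and-fire neurons
    with exponential current synapses are computed in closed form (via a
    quadratic root for tau_m = 2*tau_s and the Lambert W function for
    tau_m = tau_s), and exact analytical gradients of a time-invariant
    spike-time loss are propagated through alternating neuron and delay
    layers. Axonal, dendritic and synaptic transmission delays are
    trainable alongside synaptic weights through a bounded logistic
    reparameterization. Includes a procedural generator for the Yin-Yang
    classification task with time-to-first-spike encoding, a configurable
    hardware-noise simulation mode (spike jitter, fixed-pattern weight
    noise, parameter quantization), and an independent numerical membrane
    oracle for validating the closed forms and gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    pracma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
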