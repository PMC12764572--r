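Package: burstnet
Title: Burst-Based Spiking Vision Networks with Piecewise-Linear Neuron
    Hardware Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator for a bio-inspired spiking image-recognition stack
    built from Hindmarsh-Rose (HR) burst neurons. Provides the
    piecewise-linear substitution engine that replaces the cubic, quadratic
    and exponential nonlinearities with segment tables (including a seeded
    best-approximation search and normalized error metrics), the linear HR
    (LHR) neuron with first-order Euler integration, AMPA/GABA
    double-exponential synapses with distance-dependent coupling,
    burst-timing-dependent plasticity (BTDP) with an ISI-adaptive learning
    rate and its dopamine-gated reinforcement variant (RBTDP) driven by an
    actor-critic reward-prediction-error signal, a pseudo-retinal
    pooling/Poisson spike encoder, a three-layer classification network
    scored by output burst rates, and a bit-deterministic fixed-point
    emulation of the multiplier-less shift-and-add digital datapath.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
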