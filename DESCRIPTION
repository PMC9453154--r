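Package: sdqn
Title: Directly Trained Spiking Deep Q-Networks with Potential-Based Layer Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time leaky integrate-and-fire (LIF) spiking layers,
    potential-based layer normalization (pbLN) of the post-synaptic potential,
    and surrogate-gradient backpropagation through time for deep Q-learning
    with spiking convolutional networks. Includes closed-form predictors for
    the propagation of membrane-potential variance and spike-rate bounds in
    randomly initialized deep spiking networks, Monte-Carlo oracles that
    verify them, firing-rate diagnostics that exhibit the vanishing of spike
    features with depth and its rescue by pbLN, and a self-contained seeded
    pixel reinforcement-learning environment (catch) so the whole pipeline is
    testable on a desktop CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
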