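Package: stmnet
Title: Fixed-Point Spiking Neural Network Simulator for Theta-Gamma
    Spatio-Temporal Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bit-accurate software model of a hardware-oriented
    spatio-temporal memory spiking neural network. Provides fixed-point
    leaky integrate-and-fire neuron arithmetic, linearized
    after-depolarizing-potential (ADP) and theta-oscillation machinery
    realized as auxiliary neuron banks, assembly-coded associative and
    episodic memory network construction with hardware memory-cost
    accounting, tempotron and STDP training with post-hoc quantization, a
    1 ms time-stepped simulation engine, and robustness experiments
    (spike-time jitter, spike deletion, assembly overlap and gamma-period
    sweeps) scored with the Gaussian-filtered spike-train correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
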