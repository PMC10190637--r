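Package: evoect
Title: Simulation of an Evolvable Organic Electrochemical Transistor Pattern Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phenomenological simulator of a neuromorphic pattern classifier
    built from evolvable organic electrochemical transistors (EOECTs). Synaptic
    weights are stored as differences of two non-negative, increase-only channel
    conductances (the two-wire representation), trained by Widrow-Hoff style
    write-pulse protocols, and read non-destructively below the
    electropolymerization threshold. Includes a pulse-driven conductance growth
    model with device-to-device variability and dry-state retention drift, a
    16-pixel synapse array with zero-threshold classification of 4x4 bipolar
    patterns, hardware-faithful and idealized training protocols, an organic
    electrochemical spiking-neuron output stage with an affine f-I curve and
    cathodic spike waveform synthesis, and end-to-end experiment runners with
    structured logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
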