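Package: pfcdopa
Title: Spiking-Network Model of Dopaminergic Modulation of Prefrontal
    Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a four-column prefrontal-cortex spiking network of
    Izhikevich neurons with conductance-based AMPA/NMDA/GABA synapses,
    dopamine D1/D2 receptor neuromodulation, and a basal-ganglia-thalamic
    working-memory update loop. Runs the oculomotor delayed-response (ODR)
    task, reads out saccade decisions from motor-layer spike counts, and
    scores sessions for correct, perseverative, and random responses across
    a 3x3 grid of D1/D2 receptor stimulation levels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
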