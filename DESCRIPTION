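Package: qlincable
Title: Quasi-Linear Membrane and Cable Analysis of Cholinergic Interneuron Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and estimation tools for the quasi-linear
    (linearized) characterization of neuronal membranes and dendrites, built
    around striatal cholinergic interneurons. Provides closed-form
    frequency-domain models (quasi-linear somatic admittance, semi-infinite
    cable under partial optogenetic illumination, channelrhodopsin-2 kinetic
    transfer), matching time-domain compartmental simulators used as
    numerical oracles, cross-correlation system identification of phase and
    impedance from concatenated sinusoidal sweeps, multi-start least-squares
    parameter fitting, spike-triggered calcium transient profiling along
    dendrites, sleep slow-wave and spindle detection in local field
    potentials with peri-event conditional firing rates, synaptic response
    (EPSP/EPSC and paired-pulse ratio) measures, and synthetic-data
    generators with known ground truth for every modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
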