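Package: measim
Title: Biophysical Simulation and Burst Analysis of Neuronal Networks on Multi-Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates human iPSC-derived excitatory neuronal networks cultured on
    multi-electrode arrays (MEAs) with conductance-based Hodgkin-Huxley neurons,
    a slow afterhyperpolarization current producing spike-frequency adaptation,
    AMPA and NMDA synapses with voltage-dependent magnesium block and
    short-term depression, membrane noise, and virtual extracellular electrodes.
    Includes the matching MEA signal-analysis chain (Butterworth band-pass
    filtering, RMS-threshold spike detection, network-burst detection) and
    feature extraction (burst rate, burst duration, percentage of spikes in
    bursts, mean firing rate), plus in-silico pharmacology experiments
    (sAHP reduction, sodium/AMPA/NMDA receptor blockade), a Dravet-syndrome
    network model, and a sodium-channel modification scan engine.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    signal,
    jsonlite,
    stats,
    utils,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    arrow,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
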