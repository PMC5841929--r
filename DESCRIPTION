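Package: ca1ephys
Title: In Vivo CA1 Electrophysiology Analysis on the Linear Track
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of tetrode recordings from the dorsal CA1 pyramidal
    cell layer of freely moving rodents: position cleaning and lap
    segmentation on a linear track, post-sorting unit quality control and
    pyramidal-cell classification, occupancy-normalized rate maps with
    place-field detection and spatial metrics (spatial information,
    sparsity, directionality index), complex-spike-index and burst
    statistics, population-vector Spearman correlation analysis, Welch
    power spectral density with delta-band normalization, theta
    phase-locking circular statistics, and MUA-gated sharp-wave-ripple
    detection with threshold sweeps. Includes a fully annotated synthetic
    session generator (Gaussian place fields, theta-modulated bursty
    spiking, pink-noise LFP with injected ripple events) so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
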