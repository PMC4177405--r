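Package: popcal
Title: Population Two-Photon Calcium Imaging Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for population two-photon calcium imaging of
    visual cortex: neuropil-corrected fluorescence extraction from movie
    stacks, per-trial dF/F0 computation, classification of visually
    responsive neurons under a drifting-grating protocol (period-mean
    threshold plus one-way ANOVA), orientation-tuning and Fourier-modulation
    summaries, and half-decay kinetics of calcium transients. Includes a
    forward simulator of spiking, indicator dynamics, neuropil contamination
    and movie rendering that supplies ground truth for every stage, plus
    quantification of somatic indicator brightness and labeled-neuron
    fractions in two-channel histology images with fluorescent-bead
    normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
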