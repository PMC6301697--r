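Package: scnCoupling
Title: Dual-Coupling Oscillator Networks and EOF Analysis of SCN Bioluminescence Movies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the suprachiasmatic nucleus (SCN) as a two-lobed lattice
    of stochastic amplitude-phase oscillators coupled through two neuropeptide
    channels (VIP and AVP) with optional phase-delayed sinusoidal forcing that
    emulates co-culture with a rhythmic graft slice. Provides empirical
    orthogonal function (EOF) decomposition of pixel-level bioluminescence
    movies together with the standard circadian toolbox: chi-square
    periodogram, acrophase, Kuramoto synchronization index, 24-h spectral
    component ratio, and group statistics. A synthetic-movie generator renders
    network runs as PER2::LUC-like recordings (baseline decay, photon-counting
    noise) so the whole analysis pipeline is testable without slice data, and
    single-cell parameters can be estimated from dispersed-cell traces by
    autocorrelation fitting with a coefficient-of-variation criterion for
    self-sustained versus damped oscillators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    deSolve,
    withr,
    igraph
biocViews: Software, TimeCourse, CellBiology, Network, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
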