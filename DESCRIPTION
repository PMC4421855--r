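Package: tetherFRET
Title: Submillisecond Single-Molecule FRET of Diffusing Molecules: Simulation and Kinetic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Photon-level simulation and kinetic analysis of diffusion-based
    single-molecule FRET with alternating-laser excitation (ALEX). Simulates
    Brownian transits of liposome-tethered (or free) molecules through a 3D
    Gaussian confocal volume while the molecule switches FRET states under
    continuous-time Markov kinetics, with per-dye photobleaching. Analyses the
    resulting photon streams with dual-channel burst search, per-bin FRET
    efficiency (E) and stoichiometry (S), stoichiometry-based artifact
    filtering, trace stitching, variational-Bayes Gaussian-emission hidden
    Markov model idealization with evidence-based state-count selection,
    dwell-time and transition-density kinetics, FCS autocorrelation and
    donor-acceptor cross-correlation with exponential relaxation fits, and
    Arrhenius analysis of temperature-dependent rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
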