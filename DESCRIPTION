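Package: ssbkinetics
Title: Two-Step Competitive Binding Kinetics of SSB on Long ssDNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mean-field and stochastic models of single-stranded DNA binding
    protein (SSB) dynamics on long ssDNA under tension, built around a
    two-step competitive binding scheme in which tetramers first bind
    through a single OB-fold domain and then wrap additional nucleotides,
    with dissociation and unwrapping stimulated by neighbouring bound
    protein. Provides equilibrium and critical-concentration solvers,
    piecewise constant-force protocol simulation (incubation, rinse,
    force jumps), seedable noisy-trace generation, phase segmentation and
    exponential rate fitting, a footprint-resolved Gillespie lattice
    simulator, and RecA filamentation competition kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
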