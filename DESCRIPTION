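Package: rowerchain
Title: Hydrodynamically Coupled Rower Chains Near a No-Slip Wall
Version: 0.1.0
Authors@R: person("Rower", "Chain Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Brownian-dynamics simulator for chains of 'rower' oscillators --
    minimal bead models of motile cilia -- coupled purely through the Stokes
    flow they generate near a plane no-slip wall (Blake image system).  The
    package builds periodic chains of rowers driven by geometrically switched
    power-law traps, applies three gait-control mechanisms (extra spacing
    between groups, amplitude modulation, frequency detuning via trap-strength
    scaling), integrates the overdamped Langevin dynamics with correlated
    thermal noise, and analyses the emergent metachronal phase profiles:
    spatial Fourier decomposition of neighbour phase differences, thresholded
    chevron (wave-reversal) detection, and exact binomial tests for chevron
    preference across seeded simulation ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
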