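Package: circumroot
Title: Differential-Growth Simulation of Root Tropisms and Circumnutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional kinematic simulator of plant-root growth in
    which the apex is a chain of cylindrical cross-sections elongating at
    rates prescribed by a growth-response surface over axial distance and
    circumferential angle.  Stimulus signals (gravitropic, thigmotropic, and
    an internal resource-sensing oscillator) are emitted at the tip,
    propagate axially at finite speed, and are aggregated by a leaky
    integrator analogous to a continuous-time recurrent neural network.
    Differential elongation across the root flanks bends the apex, producing
    tropic steering and emergent circumnutation movements.  Includes obstacle
    contact handling, resource-concentration fields, quantification of
    nutation periods and amplitudes, and scripted experiments (gravitropic
    parameter sweeps, root-obstacle interplay, randomized gradient-climbing
    studies, and multi-root specialization scenarios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
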