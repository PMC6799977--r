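Package: wavecell
Title: Mechanochemical Phase-Field Simulation of Cell Migration Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples an activator-inhibitor relaxation oscillator,
    representing phosphoinositide signaling waves, to a phase-field model
    of a deformable cell with membrane tension, area conservation,
    friction and an activator-driven protrusive force.  Emergent
    migration modes (oscillatory, amoeboid-like, keratocyte-like) are
    classified from center-of-mass trajectories, and drivers are provided
    for phase diagrams in the (protrusive strength, cell size) plane,
    quasi-static bifurcation ramps, parameter-variation suites and a
    one-dimensional traveling-wave toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
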