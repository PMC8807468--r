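Package: fltsim
Title: Shear-Driven False-Lumen Thrombosis Simulation in Idealized Aortic Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale two-dimensional simulator of false-lumen thrombosis
    in idealized type B aortic dissection. Couples a pulsatile incompressible
    flow solver (non-Newtonian Quemada rheology, three-element Windkessel
    outlet, mobile intimal flap modelled as a pressure-loaded clamped beam)
    with a four-species shear-driven thrombosis model (resting and activated
    platelets, coagulant, bound platelets) in which growing thrombus feeds
    back on the flow through a Brinkman-type momentum sink. Includes geometry
    and meshing for a planar two-channel dissection analog, verification
    benchmarks against closed-form channel-flow solutions, and post-processing
    of wall shear stress, vortex structures, pressure differences and
    thrombus-growth phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
NeedsCompilation: yes
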