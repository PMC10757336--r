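Package: perfustim
Title: Digital Twin of a Perfusion and Capacitively Coupled Stimulation Bioreactor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-driven design tools for osteogenic cell-culture
    bioreactors that combine perfusion flow and capacitively coupled
    electric-field stimulation. Provides parametric voxel generators for
    lattice scaffolds (orthogonal woodpile and honeycomb), scaffold holders,
    electrode assemblies and a plate validation cell; a lumped Poiseuille
    model of the outlet channel manifold with the area-conservation design
    rule; a staggered-grid Stokes solver for creeping perfusion flow with
    shear-rate, wall shear stress and Reynolds diagnostics; a quasistatic
    frequency-domain electric-field solver with complex admittivity, a
    layered-media analytic oracle and series-resistor and terminal-current
    corrections; volume-weighted region-of-interest dose statistics against
    osteoinductive stimulation windows; and the design decision loop plus
    prediction-versus-measurement validation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
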