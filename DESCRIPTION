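Package: phasecell
Title: Three-Dimensional Phase-Field Simulation of Cell Migration on
    Curved and Porous Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A nondimensional 3D phase-field model of single-cell migration
    in which the cell is an order parameter advected by an actin polarity
    field, with an exponential membrane-tension factor that suppresses actin
    polymerization at highly curved, stretched regions of the membrane.
    Includes generators for the porous substrates used to study
    curvature-guided migration (spinodal bijel-templated microstructures via
    the Cahn-Hilliard equation, and inverse sphere-packing particle-templated
    scaffolds via layered random close packing), plus shape analytics
    (centroid displacement, inertia eigenvalues, shape energy, mean polarity,
    membrane curvature maps) and STL/CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
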