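Package: dpdwet
Title: Chemically Specific Dissipative Particle Dynamics with Smooth Walls and a Wetting Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dissipative particle dynamics (DPD) simulator for coarse-grained
    water/alkane models with smooth, featureless substrate walls, together with
    the analysis toolkit needed to parametrize surface wettability. The engine
    integrates soft repulsive bead models (including bonded 7-mer dodecane) in
    NVT and NPT ensembles, with periodic or specularly reflecting walled
    boundaries, and accumulates the virial pressure tensor including the
    wall-force contribution. Interfacial tensions and (signed) wall surface
    energies are measured from pressure-tensor anisotropy; contact angles are
    extracted from cylindrical-droplet density fields by boundary detection,
    algebraic circle fitting and extrapolation to the macroscopic radius; and
    the Young equation together with the de Gennes spreading parameter is used
    to predict, classify and invert wetting behavior as a function of the wall
    repulsion amplitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
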