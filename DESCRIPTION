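Package: tattoodose
Title: Monte Carlo Modeling of Radiotherapy Dose Perturbation by Tattoo Pigments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the perturbation of megavoltage photon and electron skin dose by
    intradermal tattoo pigments. Builds transport-ready materials from published elemental
    compositions of commercial tattoo inks (wet-to-dry conversion, compound density
    assignment, REACH compliance screening), constructs a voxelized multilayer skin phantom
    with an embedded 0.3 mm tattoo sublayer, and runs a simplified, seeded voxel Monte Carlo
    engine (Klein-Nishina Compton sampling, photoelectric and pair-production interactions,
    condensed-history electron transport with Gaussian multiple scattering) to score 3D dose
    grids. Analysis utilities compute depth-dose profiles, integrated skin dose, dose
    enhancement factors (DEF) and lateral dose maps, and a scenario runner reproduces the
    standard experiment layouts at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
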