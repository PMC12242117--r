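Package: opdensity
Title: Chemical-Bond Overlap Density and Topological Bond Descriptors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes two-center (overlap) electron density fields between
    bonded molecular fragments from Gaussian-basis molecular-orbital
    wavefunctions in the Molden format, together with their integrated
    overlap populations, intra-overlap Coulomb repulsion, and
    critical-point descriptors of both the overlap density (overlap
    critical points) and the total density (QTAIM bond critical points,
    local energy densities). Includes Becke molecular quadrature grids,
    analytic basis-function derivatives up to second order, Gaussian cube
    export, bond-axis density profiles, and a command-line interface for
    batch hydrogen-bond descriptor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
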