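Package: hipres
Title: Hydrostatic Pressure Effects on Molecular Electronic Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hydrostatic pressure on molecules with the GOSTSHYP
    model: normalized repulsive Gaussian potentials placed on a tessellated
    van der Waals cavity (optionally with an outer-cavity correction), whose
    amplitudes are determined self-consistently from the electron density.
    Includes a compact restricted Hartree-Fock engine over Gaussian basis
    sets, an integral-direct evaluation of the three-center tessera
    integrals with conservative screening, analytic nuclear gradients of
    the pressure energy, geometry optimization under pressure, and a
    counterpoise-corrected binding-energy protocol with pressure-slope
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
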