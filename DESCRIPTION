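Package: stenoflow
Title: Finite-Volume Hemodynamics of Axisymmetric Arterial Stenoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Steady laminar blood flow through parameterized cosine-shaped
    axisymmetric stenoses, solved on a boundary-fitted structured grid with a
    colocated finite-volume SIMPLE pressure-velocity coupling and either a
    constant-viscosity Newtonian or a shear-thinning Carreau constitutive
    model. Provides hemodynamic post-processing (post-stenotic recirculation
    length, wall pressure distribution and pressure drop, wall shear stress
    profile and peak), semi-analytic fully developed pipe-flow oracles for
    generalized-Newtonian fluids, and a reference case suite spanning stenosis
    degrees 0 to 0.75 at Reynolds number 300.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
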