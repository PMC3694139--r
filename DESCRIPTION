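Package: tumorperf
Title: Coupled Intravascular and Interstitial Fluid Flow in Solid Tumors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interstitial fluid pressure in a two-dimensional
    tumor/normal tissue domain coupled to blood flow through a
    tumor-induced capillary network. The network is generated by a
    discrete sprouting-angiogenesis lattice model, intravascular flow is
    solved by Poiseuille resistances with successive over-relaxation,
    blood rheology follows the empirical diameter- and
    hematocrit-dependent apparent viscosity law with plasma skimming at
    bifurcations, vessel diameters remodel under wall-shear, pressure
    and metabolic stimuli, and the vasculature is coupled to a
    finite-difference Darcy solver for the interstitium through
    Starling's law. Three solution approaches are provided: a
    uniform-source baseline without a network, a rigid-vessel coupled
    model, and a fully adaptive non-Newtonian coupled model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
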