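Package: willisflow
Title: Lattice Boltzmann Simulation of Cerebral Blood Flow in the Circle of Willis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale three-dimensional blood-flow simulator for the
    circle of Willis built on the single-relaxation-time (BGK) lattice
    Boltzmann method with a D3Q19 velocity set. Provides parametric vessel
    networks voxelised to classified lattices (including an idealised circle
    of Willis with removable posterior communicating arteries), pulsatile
    velocity inlets with five basilar-artery infarct scenarios, fixed-pressure
    outlets, and the observables used to characterise stroke flow
    redistribution: per-outlet volumetric flow rate, stroke-to-healthy flow
    ratios, velocity magnitude, and wall shear stress. Includes analytic
    validation cases (Poiseuille tube, planar Couette flow, decaying shear
    wave) and grid-convergence tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
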