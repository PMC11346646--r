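Package: vestibflow
Title: Current-Flow Modelling for Galvanic Vestibular Stimulation Montages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static volume-conduction modelling of galvanic vestibular
    stimulation (GVS). Generates synthetic voxelized head phantoms (concentric
    conductive tissue layers with small bilateral vestibular regions of
    interest), stamps circular scalp electrode pads for the seven GVS montages
    described in the literature, solves the Laplace equation div(sigma grad V)
    = 0 with current-controlled terminals by a matrix-free finite-volume
    conjugate-gradient solver, and derives the full electric-field metric
    suite: per-region mean, standard deviation and 99th-percentile field
    strength, region inflow current, left/right symmetricity ratios, the
    fraction of injected current entering the cranial cavity, inter-electrode
    separations, intensity rescaling, bootstrap confidence intervals and
    star-plot normalization. An analytic layered-sphere series solution and
    manufactured-solution harness certify the numerical solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
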