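Package: phosfem
Title: Current-Density Modelling and Phosphene-Threshold Simulation for
    Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for evaluating volume-conductor models of
    transcranial alternating-current stimulation (tACS) against phosphene
    thresholds. Builds synthetic voxelized head/eye/torso phantoms with
    10/20-style electrode montages, assembles and solves the quasi-static
    current-injection problem on trilinear hexahedral finite elements (pure
    Neumann injection or the complete electrode model), validates the solver
    against closed-form multilayer-sphere potentials, summarizes retinal and
    visual-pathway current densities over regions of interest, simulates the
    three-step phosphene-threshold staircase protocol on synthetic observer
    cohorts, and runs the rank-correlation and nonparametric test battery
    linking simulated current densities to thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
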