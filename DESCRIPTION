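Package: funcontrol
Title: Functional Controllability of fMRI Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-control-theoretic analysis of functional brain networks:
    motion-aware postprocessing of ROI BOLD timeseries (framewise displacement,
    notch filtering, censoring with contiguity constraints, 36-parameter
    nuisance regression, spectral interpolation, band-pass filtering, QC),
    sparse partial-correlation connectome estimation by graphical LASSO,
    average and modal controllability of the functional network at the ROI and
    network level, and linear mixed-effects group contrasts between diagnostic
    groups and drug conditions. Includes a seeded synthetic-cohort generator
    with network-structured VAR(1) dynamics, motion spike processes and
    nuisance components, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'connectome.R'
    'control.R'
    'models.R'
    'pipeline.R'
    'preprocess.R'
    'synth.R'
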