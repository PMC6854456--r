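Package: smstempo
Title: Temporally Regularized SENSE Reconstruction for Simultaneous
    Multi-Slice fMRI
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstruction and statistical characterization of
    simultaneous multi-slice (SMS) fMRI acquisitions with time-varying
    CAIPI sampling. Implements the spatially adaptive, temporally
    regularized SENSE reconstruction (conjugate-gradient and exact
    per-alias-group direct solvers), the encoding-dependent equivalent
    temporal smoothing operator, and analytic quality metrics: g-factor
    noise amplification, effective temporal degrees of freedom, exact
    and asymptotic GLM efficiency, tSNR efficiency, and slice-leakage
    bias. A synthetic-data suite (coil sensitivities, cylindrical
    phantoms, 1/f BOLD-like signals, task regressors, complex Gaussian
    noise) supports Monte-Carlo noise simulations and noise-free
    leakage simulations without any acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'sampling.R'
    'encoding.R'
    'groups.R'
    'solver.R'
    'cg.R'
    'synth.R'
    'io.R'
    'smoothing.R'
    'stats.R'
    'sims.R'
    'smstempo-package.R'
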