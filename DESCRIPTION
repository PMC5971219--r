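Package: fnirsDCM
Title: Dynamic Causal Modelling for Infant fNIRS with Photon-Transport
    Sensitivity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates directed (effective) connectivity from functional
    near-infrared spectroscopy recordings by dynamic causal modelling.
    Provides a finite-element solver for the continuous-wave photon
    diffusion equation on labelled tetrahedral head meshes to obtain
    channel sensitivity functions (photon measurement density functions),
    modified Beer-Lambert preprocessing with Butterworth filtering and
    motion-artifact correction, a bilinear neuronal model coupled to
    balloon hemodynamics and an augmented optics observation equation,
    variational-Laplace model inversion, fixed-effects Bayesian model
    selection and averaging over a 13-model space, and a synthetic-data
    generator with parameter- and model-recovery harnesses for an
    infant auditory block design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
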