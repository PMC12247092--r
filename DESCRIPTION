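Package: ihridme
Title: Hyperfine Spectral Diffusion Modelling and Inversion for ih-RIDME EPR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inversion of intermolecular hyperfine
    relaxation-induced dipolar modulation enhancement (ih-RIDME) pulse EPR
    data. Implements the longitudinal hyperfine spectral-diffusion kernel
    (exact PDE solution and closed-form approximation), global non-negative
    fitting of multi-mixing-time trace sets into distributions of the
    hyperfine spectrum width p(sigma) with optional Tikhonov-type
    regularization, structure-based prediction of p(sigma) from nuclear
    coordinate ensembles via the point-dipole approximation, an exact
    density-matrix simulator for small electron-nuclear spin systems used as
    a validation oracle, and a synthetic trace-set generator for numerical
    experiments.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
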