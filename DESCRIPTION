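Package: hemorom
Title: Reduced-Order Modelling of Blood Stasis in Idealized Atrial Geometries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for parametric left-atrial hemodynamics:
    a finite-volume incompressible Navier-Stokes solver with Newtonian and
    Casson (yield-stress, hematocrit-dependent) blood rheology on an idealized
    two-dimensional atrium-with-appendage geometry; passive-scalar transport of
    blood-age moments and washout; wall shear stress indices (TAWSS, OSI); and
    a non-intrusive proper-orthogonal-decomposition / radial-basis-function
    (POD-RBF) reduced-order model mapping cardiac-output scaling, plasma
    viscosity and hematocrit to all stasis indices, with uniform and Latin
    hypercube parameter designs, energy-threshold mode selection and
    relative-error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    jsonlite,
    lhs,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
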