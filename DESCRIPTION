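Package: lhflow
Title: Desk-Scale Image-Driven Left-Heart Hemodynamics with Turbulence and
    Stagnation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood flow in an idealized moving left heart (left
    ventricle, left atrium with appendage, aortic root) driven by a prescribed
    periodic wall motion, using an arbitrary Lagrangian-Eulerian incompressible
    Navier-Stokes solver with a sigma-model large-eddy subgrid viscosity and
    resistive immersed valve surfaces switched by on-off pressure/flow rules.
    Provides a synthetic anatomy-and-motion generator emulating cine-MRI derived
    inputs for a healthy and a mitral-regurgitant scenario, phase-locked
    ensemble turbulence statistics (velocity standard deviation, Reynolds
    stresses, global turbulent kinetic energy, maximum tangential stress with
    hemolysis exposure metrics, Pope LES-quality criterion), wall shear stress
    indices (TAWSS, OSI, relative residence time), the E-wave propagation
    index, and the clinical helper arithmetic (Du Bois body surface area,
    heartbeat periods, phase fractions, relative discrepancies) used to compare
    the two scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
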