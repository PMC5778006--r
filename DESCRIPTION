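Package: cbfsim
Title: Coupled Blood Flow and Oxygen Transport Modelling for Cortical
    Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state blood flow and oxygen transport in
    segmented cortical microvascular networks. Provides Poiseuille network
    flow with empirical in-vivo blood rheology (diameter- and
    haematocrit-dependent viscosity, red-blood-cell phase separation at
    bifurcations), constrained estimation of unknown boundary conditions
    against target pressures and wall shear stresses, and a Green's-function
    model of intravascular and tissue oxygen transport with Michaelis-Menten
    consumption. Includes in-silico perturbation experiments (vasoconstriction
    cascades, global arteriolar dilation, erythrocyte-deformation viscosity
    reduction) and a seeded generator of cortical-like synthetic networks for
    fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
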