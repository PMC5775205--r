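Package: crowdingLV
Title: Lotka-Volterra Competition with Nonlinear Crowding Mortality
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of Lotka-Volterra competition systems in
    which per-capita mortality rises nonlinearly with a species' own density
    (a crowding effect), plus two comparison variants: an aggregation-type
    mortality law and nonlinear (squared) interspecific competition terms.
    Provides an n-species adaptive ODE integrator, interior-equilibrium
    solving by scalar reduction, stability classification via Jacobian
    eigenvalues, two-species phase-plane isocline analysis with the four
    classical competition cases, parameter-sweep machinery over the crowding
    exponent, a registry of ready-made scenarios, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
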