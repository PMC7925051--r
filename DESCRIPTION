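Package: qifdyn
Title: Exact Mean-Field Dynamics and Bifurcations of Quadratic
    Integrate-and-Fire Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and bifurcation analysis of a two-population
    (excitatory-inhibitory) network of quadratic integrate-and-fire neurons
    with conductance-based instantaneous synapses, together with its exact
    four-dimensional mean-field reduction under the Lorentzian ansatz.
    Provides the spiking-network simulator, the mean-field integrator,
    multi-start equilibrium location with eigenvalue classification,
    limit-cycle shooting with Floquet multipliers, pseudo-arclength
    continuation of equilibria with fold and Hopf detection, two-parameter
    bifurcation-curve tracing with region counting, inter-peak-interval
    bifurcation sweeps, and largest-Lyapunov-exponent estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
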