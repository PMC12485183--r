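Package: epiosc
Title: Notch-Wnt-YAP Oscillations in Epidermal Stemness and Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic models of epidermal stem-cell (SC) and transit
    amplifying cell (TAC) dynamics. Implements a terminally-differentiated-cell
    (TDC) population model with analytic steady states and a critical
    Delta-ligand threshold; a four-variable Hill-regulated ODE network coupling
    Notch activity in the TAC, Wnt activity in the SC and TAC, and nuclear YAP
    activity in the TAC; numerical equilibrium continuation with Hopf and fold
    (limit-point) detection, oscillatory-range scans and quasi-static hysteresis
    sweeps; deterministic time-domain simulation with oscillation metrics, phase
    relations and a terminal-differentiation ablation protocol; and a
    partial-stochastic Euler-Maruyama ensemble simulator with per-trajectory
    random substreams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
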