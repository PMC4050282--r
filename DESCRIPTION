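Package: apinit
Title: Biophysics of Action Potential Initiation-Zone Dynamics in Unmyelinated Axons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental cable-equation modelling and analysis tools for studying
    how somatic depolarization reshapes the action-potential initiation zone of
    unmyelinated axons (hippocampal mossy fibres). Provides a branched
    Crank-Nicolson cable solver with Hodgkin-Huxley-type channels including a
    depolarization-sensitive slow Na+ inactivation gate, spike/latency/threshold
    analysis of somatic and axonal traces, per-spike Ca2+ entry quantification,
    a kinetic model of axonal Na+ dynamics with SBFI indicator binding and its
    staged fitting procedure, Monte Carlo simulations of stochastic initiation-site
    latencies, and generators for synthetic dual-patch and fluorescence recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
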