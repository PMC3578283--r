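Package: stpmem
Title: Associative Memory Networks with Short-Term Synaptic Depression and
    Facilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and bifurcation analysis of a Hopfield-type
    associative memory network of stochastic binary neurons whose synapses
    show short-term depression and facilitation (Tsodyks-Markram dynamics).
    Provides generation of correlated memory patterns, simulation of the
    stochastic microscopic network, the exact sublattice mean-field
    reduction to a low-dimensional deterministic map, Newton-based
    fixed-point solving with the analytic Jacobian, branch continuation in
    the noise intensity, detection and classification of saddle-node,
    Neimark-Sacker, transcritical and pitchfork bifurcations, brute-force
    mapping of quasi-periodic oscillatory regimes, and classification of
    retrieval states via overlaps and the effective dimension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
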