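Package: oncolattice
Title: Hybrid Multiscale Simulation of Vascular Tumor Growth with a
    Learning Phenotype-Decision Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid cellular-automaton model of avascular-to-vascular tumor
    growth on a 3D lattice. Discrete cell agents (healthy, cancerous, and
    endothelial tip/stalk cells) interact with five continuum fields (oxygen,
    glucose, TGF-alpha, TNF-alpha, VEGF) evolved by an explicit 26-neighbor
    reaction-diffusion scheme with vessel wall sources and phenotype-dependent
    uptake. Per-cell phenotype decisions are driven by Q-learning over a
    continuous state space, with state-action values approximated by a
    three-kernel support vector regression ensemble weighted by F-measure and
    tuned by an NSGA-II multi-objective search. Includes tumor-induced
    angiogenesis (tip/stalk sprouting, anastomosis and perfusion), a
    sub-cellular signaling layer (EGFR and TNF pathway surrogates), and an
    external-validation suite fitting Gompertz tumor growth, sigmoid vessel
    growth, and exponential branching laws with RMSE/MAD/MAPE reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
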