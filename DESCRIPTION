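Package: capflow
Title: Microvascular Network Blood Flow Simulation with Discrete Red
    Blood Cell Tracking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates steady and red-blood-cell-resolved blood flow in
    cortical microvascular networks. Provides a vascular graph data model
    with branch-order labelling, a seeded generator of synthetic cortical
    microvascular networks, empirical blood rheology laws (diameter- and
    hematocrit-dependent effective viscosity, the Fahraeus effect and
    Zweifach-Fung phase separation at divergent bifurcations), a sparse
    Poiseuille pressure solver, discrete red blood cell tracking coupled
    to the pressure field, and an in silico focal capillary dilation
    protocol that mimics pericyte ablation together with the downstream
    flow-redistribution analytics (relative flow changes, neighbor
    generations, spatial profiles, bifurcation flow steal, flow
    heterogeneity and stall censuses).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    Matrix,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    xml2
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
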