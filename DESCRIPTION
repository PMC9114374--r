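Package: neurongrowth
Title: Phase-Field Simulation of Neuron Growth with Isogeometric Collocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the early stages of neuron growth (lamellipodia
    formation, neurite outgrowth, axon differentiation and dendrite
    formation) with a phase-field model coupled to intracellular tubulin
    transport. The coupled reaction-diffusion system is solved in strong
    form by isogeometric collocation on tensor-product cubic B-splines at
    Greville abscissae, with implicit Euler time stepping and Newton-Raphson
    iteration, growth-cone energy activation zones at detected neurite tips,
    geodesic longest-neurite axon selection, and automatic multi-resolution
    domain extension. Also provides the morphometric pipeline used to
    compare simulated and traced neurite morphologies: change-point-test
    segmentation of (x,y) tracings, segment lengths and turning angles,
    summary tables and Mann-Whitney comparison of angle samples.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    splines
Config/testthat/edition: 3
RoxygenNote: 7.3.3
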