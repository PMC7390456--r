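Package: CaMKIIsim
Title: Rule-Based Kinetic Models of CaMKII Phosphorylation in the
    Postsynaptic Density
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic and stochastic simulators for the
    calcium/calmodulin/neurogranin/CaMKII/PP1 signalling network of the
    postsynaptic density. A rule set over multistate agents is expanded
    into a mass-action reaction network for monomeric CaMKII and solved
    with stiff ODE integration, or simulated network-free as discrete
    dodecameric holoenzymes with neighbour-restricted autophosphorylation
    using an exact stochastic simulation algorithm. Includes calibrated
    synthetic calcium input protocols (clamps, single spikes, 0.5 Hz
    pulse trains), dose-response scans, spike-response metrics, responder
    statistics and saturating-exponential (leaky-integrator)
    characterisation of phosphorylation build-up.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
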