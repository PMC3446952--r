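Package: retikin
Title: Mass-Action Equilibrium Analysis of the Retinol-RBP4-Transthyretin
    Homeostatic System
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for speciation analysis of the retinol carrier-protein
    network: retinol bound to retinol-binding protein 4 (RBP4), the ternary
    holo-RBP-transthyretin complex, and the apo-RBP-transthyretin complex,
    with optional competitive partitioning of retinoic acid between CRABP1
    and CRABP2.  Provides a literature-style stepwise approximation chain,
    an exact coupled mass-action equilibrium solver with an independent
    bisection oracle, RBP4 perturbation scans with percent-change metrics,
    Monte-Carlo propagation of parameter uncertainty, synthetic binding
    titrations with dissociation-constant recovery, closed-form radical
    kinetics helpers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
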