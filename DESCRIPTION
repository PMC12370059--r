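Package: tempocode
Title: Quantifying Drug Effects on Stimulus-Specific Signaling Dynamics
Version: 0.1.0
Authors@R:
    person("Temporal", "Coding Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates nuclear NFkB activity trajectories under pharmacological
    perturbation of an IkBa-NFkB negative-feedback module, reduces trajectory
    grids to interpretable feature spaces (signaling codons, non-negative
    canonical polyadic decomposition, functional principal components), and
    quantifies stimulus-response specificity with epsilon-network clustering,
    partition-alignment misclustering rates, and confusion / specificity /
    inhibition scores per drug regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
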