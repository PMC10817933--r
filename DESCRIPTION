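Package: tempdeffuant
Title: Temporal Deffuant Opinion Dynamics on Bursty Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulator for the bounded-confidence (Deffuant)
    opinion model on temporal networks, where pairwise opinion exchanges
    occur only when a social tie activates according to a per-link renewal
    process with exponential or log-normal (bursty) inter-event times.
    Provides Erdos-Renyi, Watts-Strogatz and attribute-fitness
    preferential-attachment network generators with structural statistics
    (clustering, betweenness, modularity, assortativity), degree-preserving
    configuration rewiring, epsilon-gap detection of final opinion clusters
    with a minimum-size filter, and an experiment runner for replicated
    parameter sweeps over confidence level, burstiness and network
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
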