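Package: carepath
Title: Network Modelling of Clinical Interactions Along Emergency-Department Patient Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the flow of clinical information around
    emergency-department presentations with risk of suicide or self-harm.
    Reads timestamped clinical event logs, builds directed patient-trajectory
    networks and undirected clinical interaction networks under an operational
    forbidden-edge policy, computes centrality, global efficiency and greedy
    modularity communities, assesses network vulnerability with a constrained
    connected double-edge-swap null model, node removal and greedy edge
    restoration, and identifies interactions that precipitate psychiatric
    referral with a Bernoulli naive Bayes classifier on dynamic network states,
    scored by balanced accuracy and permutation feature importance over grouped
    resampling splits. Includes a synthetic event-log generator with planted
    team structure, hub mediation and referral triggers for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
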