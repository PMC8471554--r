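Package: gcnetrank
Title: Graph-Algorithm Ranking of Granger-Causality Networks for
    Epileptic Zone Localization
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ranking intracranial-EEG electrode nodes by their
    importance to an epileptic network, starting from pairwise
    Granger-causality (GC) connectivity maps. Provides a graph data model
    for GC maps with file I/O; a bivariate time-domain Granger-causality
    stage with F-test edge pruning; Monte Carlo random-walk node sampling
    with reversed-edge, revisit-interval and multi-token variants;
    deterministic centrality rankings (weighted PageRank, betweenness,
    harmonic, in/outdegree, total-GC-outdegree); a rank-order-sum
    significance test of rankings against clinician-labelled seizure onset
    and resection zones with Monte Carlo and closed-form nulls; and a
    synthetic-data generator that plants causal-hub structure in GC maps
    and vector-autoregressive time series so the whole pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
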