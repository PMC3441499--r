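Package: gtpnet
Title: Topology, Modules and Null Models for the Small GTPase Protein
    Interaction Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses curated protein-protein interaction
    networks for the small GTPase subfamilies (Rho, Ras, Rab, Arf, Ran,
    RGK). Ingests STRING-style edge tables and SIF files, filters by
    interaction confidence, and merges per-subfamily graphs into one
    undirected simple network. Computes degree distributions with
    log-log power-law fits, clustering coefficients, shortest-path
    statistics, hub tiers from gaps in the degree sequence, and
    betweenness-based bottleneck rankings. Implements MCODE-style
    seeded-growth molecular complex detection with vertex weighting,
    haircut pruning and k-core filtering, plus degree-preserving
    edge-swap randomization for null ensembles and one-sample Z tests.
    Includes subfamily cross-talk overlap analysis, hypergeometric
    (Fisher/EASE) over-representation tests against user-supplied
    annotation tables, and seeded synthetic-network generators
    (partial duplication, preferential attachment, Erdos-Renyi, and a
    STRING-style fixture emulator) so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
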