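Package: deltateams
Title: Discovery of Spatial Gene Clusters as Delta-Teams in Weighted Graphs
Version: 0.1.0
Authors@R:
    person("deltateams", "maintainers", email = "deltateams@example.org",
           role = c("aut", "cre"))
Description: Detects delta-teams, i.e. maximal common single-linkage clusters
    under a per-graph shortest-path distance bound, in two or more weighted
    undirected graphs, with or without gene-family labels on the vertices.
    Includes a pipeline that converts Hi-C contact maps and gene annotations
    into weighted gene graphs (spatial and sequential flavours), a spatial
    gain statistic contrasting the two, a Gene Ontology based functional
    coherence penalty with empirical resampling p-values for ranking cluster
    candidates, brute-force reference oracles, and seeded synthetic data
    generators so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
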