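Package: seedpath
Title: Disease Gene Prioritization by Seed-Pair Shortest Paths in
    Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes novel disease genes from a confidence-weighted
    protein-protein interaction network and a set of known disease
    ("seed") genes. Interaction confidence scores in the STRING links
    dialect are converted to edge weights (1000 minus the combined
    score), shortest paths between all pairs of seed genes are computed
    with Dijkstra's algorithm, and every non-seed gene is scored by the
    number of seed-pair shortest paths on which it appears as an inner
    node. Candidates are filtered with an empirical permutation FDR
    obtained by rescoring random same-size seed sets. Includes synthetic
    network generators (random scored networks and planted-connector
    modules) for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
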