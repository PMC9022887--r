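Package: cytonet
Title: Disease-Specific Cytokine Profiles from Protein Interaction Network Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs disease-specific cytokine profiles from a weighted
    protein-protein interaction network. High-confidence edges are embedded
    with second-order random walks and skip-gram feature learning; cosine
    Association Scores between gene embeddings are aggregated per disease
    gene set and normalized within disease-size bins to empirical-CDF scores
    (NAAS). Profiles are summarized as category-level Immune Scores,
    validated against literature co-occurrence frequencies by Spearman rank
    correlation with permutation p-values, and turned into bipartite
    pathogenesis-cytokine subnetworks whose Immune Connection Density and
    Fiedler sign-cut spectral partition expose the key genes linking
    pathogenesis to inflammation. A seeded synthetic-world generator with
    planted network modules, disease gene sets and literature frequencies
    makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
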