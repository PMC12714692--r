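Package: topicnets
Title: Topic-Specific Gene Co-Occurrence Networks from Curated Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models gene contextuality from curated gene-set collections and
    their associated literature. Documents linked to gene sets are clustered
    into latent topics with a seeded collapsed-Gibbs LDA sampler; per topic, a
    simple undirected gene co-occurrence network is built from pairwise
    gene-set intersections. Per-gene contextual importance is quantified by
    betweenness and eigenvector centrality, local fractal dimension, and
    betweenness variance under random edge rewiring, with Louvain module
    detection, hypergeometric overrepresentation analysis, Laplacian spectral
    network comparison, and a semantic similarity map of topics (Lin
    similarity over an ontology DAG, classical multidimensional scaling).
    Includes a synthetic-fixture generator with planted topics, set overlaps,
    and hub genes so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    stringi,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
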