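# Global topological summaries and Laplacian spectral comparison of topic
# networks.

#' Global topological metrics of a topic network
#'
#' Summarizes a network by node/edge counts, average degree, clustering
#' coefficient (global transitivity by default), density, diameter and
#' average path length (both computed on the largest connected component),
#' Louvain modularity (at `louvain_seed`), and mean node betweenness and
#' mean harmonic closeness.
#'
#' @param net A non-empty `topic_network`.
#' @param louvain_seed Seed for the Louvain partition behind the modularity
#'   entry (default 1).
#' @param clustering Either `"global"` (transitivity: 3 x triangles /
#'   connected triples) or `"average_local"` (mean local clustering
#'   coefficient).
#' @return One-row data frame with columns `topic`, `n_nodes`, `n_edges`,
#'   `avg_degree`, `clustering`, `density`, `diameter`, `avg_path_length`,
#'   `modularity`, `avg_betweenness`, `avg_closeness`.
#' @export
global_metrics <- function(net, louvain_seed = 1L,
                           clustering = c("global", "average_local")) {
  stopifnot(inherits(net, "topic_network"))
  clustering <- match.arg(clustering)
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  m <- igraph::ecount(g)

  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize))
  )
  clus <- if (clustering == "global") {
    igraph::transitivity(g, type = "global")
  } else {
    mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  }
  if (is.nan(clus)) clus <- 0

  part <- louvain_partition(net, seed = louvain_seed)

  data.frame(
    topic = net$topic,
    n_nodes = n,
    n_edges = m,
    avg_degree = 2 * m / n,
    clustering = clus,
    density = if (n > 1L) 2 * m / (n * (n - 1)) else 0,
    diameter = igraph::diameter(giant, unconnected = FALSE),
    avg_path_length = if (igraph::vcount(giant) > 1L) {
      igraph::mean_distance(giant, unconnected = FALSE)
    } else 0,
    modularity = part$modularity,
    avg_betweenness = mean(betweenness_centrality(net)),
    avg_closeness = mean(igraph::harmonic_centrality(g, normalized = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Truncated Laplacian spectrum of a topic network
#'
#' Eigenvalues of the combinatorial Laplacian `L = D - A`. The `m` largest
#' are kept in descending order (the dominant spectral content); if the
#' network has fewer than `m` nodes the spectrum is zero-padded to length
#' `m`. `order = "smallest"` keeps the `m` smallest eigenvalues (descending,
#' zero-padded) instead.
#'
#' @param net A non-empty `topic_network`.
#' @param m Signature length (default 20).
#' @param order `"largest"` (default) or `"smallest"` truncation.
#' @return Object of class `spectral_signature`: list with `topic` and
#'   `eigenvalues` (length `m`, non-negative, non-increasing).
#' @export
laplacian_spectrum <- function(net, m = 20L, order = c("largest", "smallest")) {
  stopifnot(inherits(net, "topic_network"))
  order <- match.arg(order)
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("empty network")
  L <- igraph::laplacian_matrix(g, sparse = FALSE)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values  # descending
  ev <- pmax(ev, 0)  # clip numerical negatives near zero
  kept <- if (order == "largest") {
    utils::head(ev, m)
  } else {
    sort(utils::tail(ev, m), decreasing = TRUE)
  }
  if (length(kept) < m) kept <- c(kept, rep(0, m - length(kept)))
  structure(list(topic = net$topic, eigenvalues = kept),
            class = "spectral_signature")
}

#' Pairwise Euclidean distances between spectral signatures
#'
#' @param sigs List of `spectral_signature` objects of equal length (or a
#'   numeric matrix with one signature per row).
#' @return Symmetric numeric matrix of Euclidean distances with zero
#'   diagonal; dimnames carry topic labels when available.
#' @export
spectral_distance_matrix <- function(sigs) {
  if (is.list(sigs) && !is.data.frame(sigs) && !is.matrix(sigs)) {
    lens <- vapply(sigs, function(s) length(s$eigenvalues), integer(1))
    if (length(unique(lens)) > 1L) {
      stop("spectral signatures have mismatched lengths: ",
           paste(unique(lens), collapse = ", "))
    }
    mat <- do.call(rbind, lapply(sigs, function(s) s$eigenvalues))
    rownames(mat) <- vapply(sigs, function(s) {
      if (is.na(s$topic)) "" else paste0("topic_", s$topic)
    }, character(1))
  } else {
    mat <- as.matrix(sigs)
  }
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  diag(d) <- 0
  d
}
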