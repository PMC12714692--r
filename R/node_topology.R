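# Per-gene topology: betweenness and eigenvector centrality, local fractal
# dimension, betweenness variance under random edge rewiring, unit-interval
# rescaling, and gene-set-level aggregation.

#' Betweenness centrality of every node
#'
#' Unnormalized shortest-path betweenness (Brandes), undirected convention:
#' each unordered pair of endpoints is counted once.
#'
#' @param net A non-empty `topic_network`.
#' @return Named numeric vector, gene -> betweenness.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "topic_network"))
  if (igraph::vcount(net$graph) == 0L) stop("empty network")
  igraph::betweenness(net$graph, directed = FALSE, normalized = FALSE)
}

#' Eigenvector centrality of every node
#'
#' Dominant eigenvector of the adjacency matrix, computed by power
#' iteration on `A + I` (the shift removes the sign oscillation of
#' bipartite graphs without changing eigenvectors). Entries are
#' non-negative and rescaled so the maximum is 1.
#'
#' @param net A non-empty `topic_network`.
#' @param tol Convergence tolerance on the max-normalized iterate (default
#'   1e-10).
#' @param max_iter Maximum iterations (default 10000).
#' @return Named numeric vector in `[0, 1]`, gene -> centrality.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(net, "topic_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  if (n == 1L) return(stats::setNames(1, igraph::V(g)$name))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x  # (A + I) x
    y <- y / max(y)
    if (max(abs(y - x)) < tol) {
      return(stats::setNames(y, igraph::V(g)$name))
    }
    x <- y
  }
  stop("eigenvector centrality did not converge within max_iter = ", max_iter)
}

#' Log-log slope of a neighborhood growth profile
#'
#' Least-squares slope of `log(counts)` against `log(r)` (natural
#' logarithms). Returns 0 when fewer than two points are available.
#'
#' @param counts Cumulative neighborhood sizes `M(r)` (positive).
#' @param r Radii (default `1, 2, ...`).
#' @return The fitted slope.
#' @export
lfd_from_counts <- function(counts, r = seq_along(counts)) {
  stopifnot(length(counts) == length(r))
  if (length(counts) < 2L) return(0)
  if (any(counts <= 0) || any(r <= 0)) {
    stop("counts and radii must be positive")
  }
  x <- log(r)
  y <- log(counts)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Local fractal dimension of a node
#'
#' Measures how fast a node's neighborhood grows with distance: with
#' `M(r)` the number of nodes at shortest-path distance at most `r`
#' (excluding the node itself), the LFD is the least-squares slope of
#' `log M(r)` versus `log r` over radii 1 through
#' `min(eccentricity, r_cap)`.
#' Nodes with eccentricity below 2 (fewer than two usable radii) score 0.
#'
#' @param net A `topic_network`.
#' @param gene Gene symbol (must be a network node).
#' @param r_cap Maximum radius considered (default 10).
#' @return The local fractal dimension (a non-negative scalar).
#' @export
local_fractal_dimension <- function(net, gene, r_cap = 10L) {
  stopifnot(inherits(net, "topic_network"))
  nodes <- network_nodes(net)
  if (!(gene %in% nodes)) stop("gene not in network: ", gene)
  d <- as.numeric(igraph::distances(net$graph, v = gene))
  .lfd_from_distances(d, r_cap)
}

# shared kernel: d = distances from one node to all nodes (including 0 to
# itself, Inf off-component)
.lfd_from_distances <- function(d, r_cap = 10L) {
  d <- d[is.finite(d) & d > 0]
  if (length(d) == 0L) return(0)
  ecc <- max(d)
  rmax <- min(ecc, r_cap)
  if (rmax < 2) return(0)
  r <- seq_len(rmax)
  counts <- vapply(r, function(ri) sum(d <= ri), numeric(1))
  lfd_from_counts(counts, r)
}

#' Perturbation settings for edge rewiring
#'
#' @param n_iter Number of independent perturbation iterations (default
#'   1000).
#' @param rewire_rate Fraction of edges rewired per iteration (default
#'   0.001, i.e. 1 per mille); at least one edge is always rewired.
#' @param seed Integer seed.
#' @return Object of class `perturbation_config`.
#' @export
perturbation_config <- function(n_iter = 1000L, rewire_rate = 0.001,
                                seed = 1L) {
  stopifnot(n_iter >= 1L, rewire_rate >= 0, rewire_rate <= 1)
  structure(
    list(n_iter = as.integer(n_iter), rewire_rate = rewire_rate,
         seed = as.integer(seed)),
    class = "perturbation_config"
  )
}

#' Betweenness variance under random edge rewiring
#'
#' Repeatedly perturbs the network and records how each gene's betweenness
#' responds. Every iteration starts from the original graph and rewires
#' `max(1, round(rewire_rate * |E|))` edges: each rewiring deletes a
#' uniformly chosen current edge and inserts an edge between a uniformly
#' chosen currently non-adjacent node pair (no self-loops, no duplicate
#' edges; if no non-adjacent pair exists the deleted edge is restored, so
#' complete graphs are left unchanged). Node set and edge count are
#' preserved in every iteration. Raw betweenness is recomputed per
#' iteration and the per-gene population variance (denominator `n_iter`)
#' across iterations is returned, keyed by the original node set.
#'
#' @param net A `topic_network` with at least one edge.
#' @param cfg A [perturbation_config()].
#' @param detail If `TRUE`, also return the full betweenness matrix, the
#'   per-iteration edge counts, and the number of rewirings per iteration.
#' @return Named numeric vector of variances (gene -> variance), or, with
#'   `detail = TRUE`, a list with elements `variance`, `betweenness`
#'   (nodes x iterations matrix), `n_edges` (per-iteration edge counts),
#'   `n_rewired` (rewirings per iteration).
#' @export
perturb_and_score <- function(net, cfg = perturbation_config(),
                              detail = FALSE) {
  stopifnot(inherits(net, "topic_network"),
            inherits(cfg, "perturbation_config"))
  g <- net$graph
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0L) stop("network has no edges")
  nodes <- igraph::V(g)$name
  el0 <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el0) <- "integer"
  adj0 <- matrix(FALSE, n, n)
  adj0[el0] <- TRUE
  adj0[el0[, c(2L, 1L)]] <- TRUE
  n_rw <- max(1L, as.integer(round(cfg$rewire_rate * m)))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  btw <- matrix(NA_real_, n, cfg$n_iter, dimnames = list(nodes, NULL))
  edge_counts <- integer(cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    el <- el0
    adj <- adj0
    for (r in seq_len(n_rw)) {
      e <- sample.int(nrow(el), 1L)
      a <- el[e, 1L]
      b <- el[e, 2L]
      adj[a, b] <- FALSE
      adj[b, a] <- FALSE
      pair <- .sample_nonadjacent(adj, n)
      el[e, ] <- pair
      adj[pair[1L], pair[2L]] <- TRUE
      adj[pair[2L], pair[1L]] <- TRUE
    }
    gi <- igraph::make_graph(as.vector(t(el)), n = n, directed = FALSE)
    edge_counts[it] <- igraph::ecount(gi)
    btw[, it] <- igraph::betweenness(gi, directed = FALSE, normalized = FALSE)
  }
  mu <- rowMeans(btw)
  variance <- rowMeans((btw - mu)^2)  # population variance, ddof 0
  names(variance) <- nodes
  if (detail) {
    list(variance = variance, betweenness = btw, n_edges = edge_counts,
         n_rewired = n_rw)
  } else {
    variance
  }
}

# uniformly sample a currently non-adjacent unordered node pair; rejection
# sampling with an exhaustive-enumeration fallback (rare, dense graphs).
.sample_nonadjacent <- function(adj, n) {
  for (try in 1:100) {
    i <- sample.int(n, 1L)
    j <- sample.int(n, 1L)
    if (i != j && !adj[i, j]) return(c(i, j))
  }
  free <- which(!adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(free) == 0L) stop("no non-adjacent node pair available")
  pick <- free[sample.int(nrow(free), 1L), ]
  c(pick[[1L]], pick[[2L]])
}

#' Min-max rescaling to the unit interval
#'
#' `(x - min) / (max - min)`; a constant vector maps to 0.5 everywhere.
#' With `open = TRUE` the result is squeezed into the open interval
#' `(0, 1)` as `y * (1 - 2 * eps) + eps`.
#'
#' @param values Named numeric vector.
#' @param open Avoid exact 0 and 1 (default `FALSE`).
#' @param eps Margin used when `open = TRUE`.
#' @return Rescaled vector, same names and order.
#' @export
rescale_unit_interval <- function(values, open = FALSE, eps = 1e-9) {
  stopifnot(length(values) >= 1L)
  rng <- range(values)
  out <- if (rng[1] == rng[2]) {
    rep(0.5, length(values))
  } else {
    (values - rng[1]) / (rng[2] - rng[1])
  }
  if (open) out <- out * (1 - 2 * eps) + eps
  stats::setNames(out, names(values))
}

#' Per-gene topology table of a topic network
#'
#' Computes, for every node: raw betweenness, eigenvector centrality, local
#' fractal dimension, and betweenness variance under edge rewiring, plus
#' the four min-max-rescaled counterparts (rescaled per network so metrics
#' are comparable across networks of different size).
#'
#' @param net A non-empty `topic_network`.
#' @param perturb A [perturbation_config()] for the variance column.
#' @param r_cap Radius cap for the local fractal dimension (default 10).
#' @return Data frame with one row per gene: `topic`, `gene`, the four
#'   `*_raw` columns and the four `*_scaled` columns (each in `[0, 1]`).
#' @export
node_metrics_table <- function(net, perturb = perturbation_config(),
                               r_cap = 10L) {
  stopifnot(inherits(net, "topic_network"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  if (length(nodes) == 0L) stop("empty network")
  btw <- betweenness_centrality(net)
  eig <- eigenvector_centrality(net)
  dmat <- igraph::distances(g)
  lfd <- vapply(seq_along(nodes), function(i) {
    .lfd_from_distances(as.numeric(dmat[i, ]), r_cap)
  }, numeric(1))
  names(lfd) <- nodes
  var_btw <- perturb_and_score(net, perturb)
  data.frame(
    topic = net$topic,
    gene = nodes,
    betweenness_raw = as.numeric(btw[nodes]),
    eigenvector_raw = as.numeric(eig[nodes]),
    lfd_raw = as.numeric(lfd[nodes]),
    btw_variance_raw = as.numeric(var_btw[nodes]),
    betweenness_scaled = as.numeric(rescale_unit_interval(btw[nodes])),
    eigenvector_scaled = as.numeric(rescale_unit_interval(eig[nodes])),
    lfd_scaled = as.numeric(rescale_unit_interval(lfd[nodes])),
    btw_variance_scaled = as.numeric(rescale_unit_interval(var_btw[nodes])),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Gene-set-level topology score in a topic network
#'
#' Aggregates a rescaled node metric over the genes of a gene set that are
#' present in the network, normalizing for overlap and network size: the
#' score is the mean rescaled metric over the overlap and the coverage is
#' `|overlap| / |network nodes|`.
#'
#' @param table Node metrics table from [node_metrics_table()].
#' @param set Character vector of gene symbols (one gene set).
#' @param metric Name of a rescaled column (one of `betweenness_scaled`,
#'   `eigenvector_scaled`, `lfd_scaled`, `btw_variance_scaled`).
#' @return List with `score` (mean rescaled metric over the overlap; `NA`
#'   with a `defined = FALSE` flag when the overlap is empty), `n_overlap`,
#'   `coverage`, `defined`.
#' @export
geneset_topology_score <- function(table, set,
                                   metric = c("betweenness_scaled",
                                              "eigenvector_scaled",
                                              "lfd_scaled",
                                              "btw_variance_scaled")) {
  metric <- match.arg(metric)
  overlap <- intersect(unique(set), table$gene)
  if (length(overlap) == 0L) {
    return(list(score = NA_real_, n_overlap = 0L, coverage = 0,
                defined = FALSE))
  }
  vals <- table[[metric]][match(overlap, table$gene)]
  list(score = mean(vals), n_overlap = length(overlap),
       coverage = length(overlap) / nrow(table), defined = TRUE)
}
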