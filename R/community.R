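# Louvain module detection, per-module topology, and hypergeometric
# overrepresentation analysis with Benjamini-Hochberg correction.

#' Louvain module partition of a topic network
#'
#' Multi-level (Louvain) modularity optimization at resolution 1. Module ids
#' are relabeled to be contiguous from 0 in order of first appearance over
#' the vertex sequence, and the run is deterministic for a given seed.
#'
#' @param net A non-empty `topic_network`.
#' @param seed Integer seed (Louvain visits vertices in random order).
#' @return Object of class `module_partition`: list with `topic`,
#'   `assignment` (named integer vector, gene -> module id), `modularity`,
#'   `seed`.
#' @export
louvain_partition <- function(net, seed = 1L) {
  stopifnot(inherits(net, "topic_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("empty network")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = 1)
  memb <- igraph::membership(cl)
  ids <- unique(as.integer(memb))
  relabel <- stats::setNames(seq_along(ids) - 1L, ids)
  assignment <- stats::setNames(
    as.integer(relabel[as.character(as.integer(memb))]),
    igraph::V(g)$name
  )
  structure(
    list(topic = net$topic, assignment = assignment,
         modularity = igraph::modularity(g, memb), seed = as.integer(seed)),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition: topic =", x$topic, "|",
      length(unique(x$assignment)), "modules over", length(x$assignment),
      "genes; modularity =", signif(x$modularity, 4), "\n")
  invisible(x)
}

#' Topological metrics of each module's induced subgraph
#'
#' For each module: within-module node and edge counts, average degree,
#' density, and average path length (on the module's largest connected
#' component; 0 for singleton modules, whose density is 0 by convention).
#'
#' @param net A `topic_network`.
#' @param partition A `module_partition` covering the network's nodes.
#' @return Data frame with one row per module: `topic`, `module`, `n_nodes`,
#'   `n_edges`, `avg_degree`, `density`, `avg_path_length`.
#' @export
module_metrics <- function(net, partition) {
  stopifnot(inherits(net, "topic_network"),
            inherits(partition, "module_partition"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  if (!setequal(nodes, names(partition$assignment))) {
    stop("partition does not cover the network's node set")
  }
  mods <- sort(unique(partition$assignment))
  rows <- lapply(mods, function(mod) {
    members <- names(partition$assignment)[partition$assignment == mod]
    sub <- igraph::induced_subgraph(g, members)
    n <- igraph::vcount(sub)
    m <- igraph::ecount(sub)
    comp <- igraph::components(sub)
    giant <- igraph::induced_subgraph(
      sub, which(comp$membership == which.max(comp$csize))
    )
    data.frame(
      topic = net$topic, module = mod, n_nodes = n, n_edges = m,
      avg_degree = if (n > 0L) 2 * m / n else 0,
      density = if (n > 1L) 2 * m / (n * (n - 1)) else 0,
      avg_path_length = if (igraph::vcount(giant) > 1L) {
        igraph::mean_distance(giant, unconnected = FALSE)
      } else 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` are
#' annotated: `P(X >= k)`.
#'
#' @param k Observed overlap.
#' @param K Annotated genes in the universe (term size).
#' @param n Drawn genes (module size).
#' @param N Universe size.
#' @return The p-value (1 when `k = 0`).
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 0, n <= N, k >= 0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `p_adj(i) = min over { j : p(j) >= p(i) } of min(1, m * p(j) / rank(j))`.
#' Input order is preserved and adjustment is monotone in the p-value order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overrepresentation analysis of a module
#'
#' Tests each annotation term for overrepresentation in a gene module. All
#' gene lists are first intersected with the universe; for each term,
#' `k = |module & term|`, `K = |term|`, `n = |module|`, `N = |universe|`
#' (post-intersection), the upper-tail hypergeometric p-value is computed,
#' and the Benjamini-Hochberg adjustment is applied across all terms tested
#' for this module.
#'
#' @param module_genes Character vector of genes in the module.
#' @param terms Named list of character gene vectors (annotation collection,
#'   e.g. from [read_gmt()]); an optional `"description"` attribute supplies
#'   term names.
#' @param universe Character vector: the background gene universe.
#' @return Data frame sorted by `p`, one row per term: `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
hypergeometric_ora <- function(module_genes, terms, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  stopifnot(is.list(terms), !is.null(names(terms)))
  descs <- attr(terms, "description")
  module_genes <- intersect(unique(module_genes), universe)
  n <- length(module_genes)
  N <- length(universe)
  rows <- lapply(names(terms), function(tid) {
    term_genes <- intersect(unique(terms[[tid]]), universe)
    K <- length(term_genes)
    k <- length(intersect(module_genes, term_genes))
    data.frame(
      term_id = tid,
      term_name = if (!is.null(descs) && tid %in% names(descs)) {
        descs[[tid]]
      } else tid,
      k = k, K = K, n = n, N = N,
      p = hypergeom_pvalue(k, K, n, N),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p, out$term_id), , drop = FALSE]
}
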