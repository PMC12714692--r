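# Topic-specific gene co-occurrence networks from pairwise gene-set
# intersections.

#' Construct a topic network from an edge list
#'
#' Low-level constructor: builds a simple undirected unweighted
#' `topic_network` from a two-column character matrix of edges. Self-loops
#' and duplicate edges are removed; the node set is exactly the set of edge
#' endpoints.
#'
#' @param edges Two-column character matrix (or data frame) of gene-symbol
#'   pairs; may have zero rows.
#' @param topic Integer topic label (default `NA`).
#' @param provenance Character vector of contributing set ids.
#' @return An object of class `topic_network`: list with elements `topic`,
#'   `graph` (an igraph object with named vertices), `provenance`.
#' @export
topic_network <- function(edges, topic = NA_integer_,
                          provenance = character(0)) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) {
    storage.mode(edges) <- "character"
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  structure(
    list(topic = as.integer(topic), graph = g,
         provenance = as.character(provenance)),
    class = "topic_network"
  )
}

#' @export
print.topic_network <- function(x, ...) {
  cat("topic_network: topic =", x$topic, "|", igraph::vcount(x$graph),
      "nodes,", igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Node names of a topic network
#'
#' @param net A `topic_network`.
#' @return Character vector of gene symbols.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "topic_network"))
  igraph::V(net$graph)$name
}

#' Edge list of a topic network
#'
#' @param net A `topic_network`.
#' @return Two-column character matrix (`gene_a`, `gene_b`), each unordered
#'   edge once.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "topic_network"))
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  colnames(el) <- c("gene_a", "gene_b")
  el
}

#' Build a topic-specific gene co-occurrence network
#'
#' For every unordered pair of distinct gene sets assigned to the topic, the
#' pairwise intersection is computed and every pair of distinct genes within
#' that intersection becomes an undirected edge (a clique over the
#' intersection). Edges recurring across set pairs are collapsed to a single
#' unweighted connection. Nodes are exactly the edge endpoints: a gene that
#' never shares an intersection of size >= 2 with another gene is excluded.
#'
#' @param sets Named list of character gene vectors (the sets assigned to
#'   one topic). Zero or one set yields an empty network.
#' @param topic Integer topic label stored on the result.
#' @return A `topic_network`.
#' @export
build_topic_network <- function(sets, topic = NA_integer_) {
  stopifnot(is.list(sets))
  n <- length(sets)
  edge_keys <- new.env(hash = TRUE, parent = emptyenv())
  ea <- character(0)
  eb <- character(0)
  if (n >= 2L) {
    sets <- lapply(sets, unique)
    for (s in seq_len(n - 1L)) {
      for (t in seq.int(s + 1L, n)) {
        inter <- intersect(sets[[s]], sets[[t]])
        m <- length(inter)
        if (m < 2L) next
        inter <- sort(inter, method = "radix")
        for (a in seq_len(m - 1L)) {
          for (b in seq.int(a + 1L, m)) {
            key <- paste0(inter[[a]], "\r", inter[[b]])
            if (!exists(key, envir = edge_keys, inherits = FALSE)) {
              assign(key, TRUE, envir = edge_keys)
              ea <- c(ea, inter[[a]])
              eb <- c(eb, inter[[b]])
            }
          }
        }
      }
    }
  }
  topic_network(cbind(ea, eb), topic = topic,
                provenance = if (is.null(names(sets))) character(0) else names(sets))
}

#' Write a topic network's edge list as TSV
#'
#' @param net A `topic_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  el <- as.data.frame(network_edges(net), stringsAsFactors = FALSE)
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
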