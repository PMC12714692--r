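# Semantic similarity map of topics: information-content (Lin) similarity
# over an ontology DAG, classical MDS embedding, per-topic centroids.

#' Construct an ontology DAG with gene annotations
#'
#' @param parent_edges Two-column data frame or matrix (`child`, `parent`)
#'   of term ids; must be acyclic.
#' @param annotations Named list of character gene vectors (term id ->
#'   directly annotated genes). Terms appearing only here are added as
#'   isolated terms.
#' @return Object of class `ontology_dag`: list with `terms`, `parents`
#'   (term -> character vector of parents), `children`, `annotations`.
#' @export
ontology_dag <- function(parent_edges, annotations = list()) {
  parent_edges <- as.matrix(parent_edges)
  if (ncol(parent_edges) != 2L) stop("parent_edges must have two columns")
  storage.mode(parent_edges) <- "character"
  terms <- unique(c(as.vector(parent_edges), names(annotations)))
  parents <- lapply(stats::setNames(terms, terms), function(t) {
    unique(parent_edges[parent_edges[, 1L] == t, 2L])
  })
  children <- lapply(stats::setNames(terms, terms), function(t) {
    unique(parent_edges[parent_edges[, 2L] == t, 1L])
  })
  # acyclicity check (Kahn)
  indeg <- vapply(parents, length, integer(1))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  indeg_work <- indeg
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) stop("ontology edges contain a cycle")
  anns <- lapply(annotations, function(g) unique(as.character(g)))
  structure(
    list(terms = terms, parents = parents, children = children,
         annotations = anns),
    class = "ontology_dag"
  )
}

#' Read an ontology DAG from files
#'
#' @param edges_path Two-column TSV (`child_id`, `parent_id`), with or
#'   without a header line named `child`/`parent` (detected).
#' @param annotations_path GMT file mapping term ids to annotated genes.
#' @return An `ontology_dag`.
#' @export
read_ontology <- function(edges_path, annotations_path) {
  tab <- utils::read.delim(edges_path, header = FALSE, sep = "\t",
                           quote = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) > 0L &&
      tolower(tab[1L, 1L]) %in% c("child", "child_id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  anns <- read_gmt(annotations_path)
  ontology_dag(tab[, 1:2], as.list(anns))
}

# genes annotated to a term or any of its descendants, memoized
.term_closures <- function(dag) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  closure <- function(t) {
    if (exists(t, envir = cache, inherits = FALSE)) {
      return(get(t, envir = cache, inherits = FALSE))
    }
    assign(t, character(0), envir = cache)  # guard (DAG: no true cycles)
    genes <- dag$annotations[[t]]
    if (is.null(genes)) genes <- character(0)
    for (ch in dag$children[[t]]) genes <- union(genes, closure(ch))
    assign(t, genes, envir = cache)
    genes
  }
  stats::setNames(lapply(dag$terms, closure), dag$terms)
}

#' Information content of every term
#'
#' `IC(t) = -log(|genes annotated to t or its descendants| / |genes
#' annotated anywhere|)` (natural log). Terms with an empty annotation
#' closure get `NA`.
#'
#' @param dag An `ontology_dag`.
#' @return Named numeric vector, term -> information content.
#' @export
term_ic <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  closures <- .term_closures(dag)
  total <- length(unique(unlist(dag$annotations, use.names = FALSE)))
  if (total == 0L) stop("ontology has no annotated genes")
  vapply(closures, function(g) {
    if (length(g) == 0L) NA_real_ else -log(length(g) / total)
  }, numeric(1))
}

# ancestors of a term, including the term itself
.term_ancestors <- function(dag, t) {
  out <- character(0)
  queue <- t
  while (length(queue) > 0L) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    if (cur %in% out) next
    out <- c(out, cur)
    queue <- c(queue, dag$parents[[cur]])
  }
  out
}

#' Lin semantic similarity matrix of ontology terms
#'
#' `sim(a, b) = 2 * IC(MICA) / (IC(a) + IC(b))`, where the MICA is the
#' common ancestor of `a` and `b` (each term counts as its own ancestor)
#' with maximal information content. `sim(t, t) = 1`; when
#' `IC(a) + IC(b) = 0` (two fully annotated roots) the similarity is 1 for
#' `a = b` and 0 otherwise; term pairs with no (finite-IC) common ancestor
#' score 0.
#'
#' @param terms Character vector of term ids (all must be in the DAG).
#' @param dag An `ontology_dag`.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal, dimnames =
#'   `terms`.
#' @export
term_similarity_matrix <- function(terms, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  unknown <- setdiff(terms, dag$terms)
  if (length(unknown) > 0L) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  }
  ic <- term_ic(dag)
  anc <- lapply(stats::setNames(terms, terms), function(t) {
    .term_ancestors(dag, t)
  })
  n <- length(terms)
  sim <- matrix(0, n, n, dimnames = list(terms, terms))
  diag(sim) <- 1
  if (n < 2L) return(sim)
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      ta <- terms[[a]]
      tb <- terms[[b]]
      ica <- ic[[ta]]
      icb <- ic[[tb]]
      common <- intersect(anc[[ta]], anc[[tb]])
      common_ic <- ic[common]
      common_ic <- common_ic[is.finite(common_ic)]
      s <- if (is.na(ica) || is.na(icb) || length(common_ic) == 0L) {
        0
      } else if (ica + icb == 0) {
        0  # distinct fully annotated roots
      } else {
        2 * max(common_ic) / (ica + icb)
      }
      sim[a, b] <- s
      sim[b, a] <- s
    }
  }
  sim
}

#' Pool and rank a topic's enriched terms
#'
#' Pools the enrichment rows of all modules of one topic, deduplicates
#' terms keeping each term's best row, sorts by adjusted p-value
#' (ties: raw p, then term id), and returns the first `n` term ids.
#'
#' @param enrichment Data frame of enrichment rows for one topic (needs
#'   columns `term_id`, `p`, `p_adj`).
#' @param n Number of terms to keep (default 100).
#' @return Character vector of at most `n` term ids.
#' @export
select_top_terms <- function(enrichment, n = 100L) {
  if (is.null(enrichment) || nrow(enrichment) == 0L) return(character(0))
  ord <- order(enrichment$p_adj, enrichment$p, enrichment$term_id,
               method = "radix")
  enrichment <- enrichment[ord, , drop = FALSE]
  enrichment <- enrichment[!duplicated(enrichment$term_id), , drop = FALSE]
  utils::head(enrichment$term_id, n)
}

#' Classical (Torgerson) multidimensional scaling of a similarity matrix
#'
#' Converts similarities to distances (`d = 1 - sim`), double-centers the
#' squared distances (`B = -J d^2 J / 2`), and embeds on the leading
#' eigenvectors scaled by the square roots of their (non-negative-clipped)
#' eigenvalues. Each axis carries a deterministic sign: its first nonzero
#' coordinate is non-negative.
#'
#' @param similarity Symmetric similarity matrix in `[0, 1]` with unit
#'   diagonal.
#' @param dims Embedding dimension (default 2).
#' @return Numeric matrix (terms x dims) of coordinates, rownames from
#'   `similarity`.
#' @export
classical_mds <- function(similarity, dims = 2L) {
  similarity <- as.matrix(similarity)
  if (!isSymmetric(unname(similarity), tol = 1e-10)) {
    stop("similarity matrix must be symmetric")
  }
  if (any(similarity < -1e-12) || any(similarity > 1 + 1e-12)) {
    stop("similarities must lie in [0, 1]")
  }
  if (any(abs(diag(similarity) - 1) > 1e-12)) {
    stop("similarity matrix must have a unit diagonal")
  }
  n <- nrow(similarity)
  d <- 1 - similarity
  d2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- pmax(eig$values[seq_len(dims)], 0)
  coords <- eig$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(vals), nrow = dims)
  for (j in seq_len(dims)) {
    col <- coords[, j]
    nz <- which(abs(col) > 1e-12)
    if (length(nz) > 0L && col[nz[[1L]]] < 0) coords[, j] <- -col
  }
  rownames(coords) <- rownames(similarity)
  colnames(coords) <- paste0("dim", seq_len(dims))
  coords
}

#' Per-topic centroids in the semantic map
#'
#' @param coords Coordinate matrix from [classical_mds()] (rownames are
#'   term ids).
#' @param topic_terms Named list: topic label -> character vector of term
#'   ids (all must have coordinates). Topics with no terms are omitted with
#'   a warning.
#' @return Data frame with one row per topic: `topic`, one column per
#'   embedding dimension.
#' @export
topic_centroids <- function(coords, topic_terms) {
  stopifnot(is.matrix(coords), is.list(topic_terms))
  keep <- vapply(topic_terms, length, integer(1)) > 0L
  if (any(!keep)) {
    warning("omitting topic(s) with no terms: ",
            paste(names(topic_terms)[!keep], collapse = ", "))
  }
  topic_terms <- topic_terms[keep]
  rows <- lapply(names(topic_terms), function(tp) {
    terms <- topic_terms[[tp]]
    missing <- setdiff(terms, rownames(coords))
    if (length(missing) > 0L) {
      stop("term(s) without coordinates: ", paste(missing, collapse = ", "))
    }
    ctr <- colMeans(coords[terms, , drop = FALSE])
    cbind(data.frame(topic = tp, stringsAsFactors = FALSE),
          as.data.frame(as.list(ctr)))
  })
  do.call(rbind, rows)
}
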