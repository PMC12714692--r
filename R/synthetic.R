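# Synthetic corpora, gene-set collections, and benchmark graphs with
# planted structure, so every pipeline stage runs and is checkable offline.

# Synthetic vocabulary tokens are spelled with consonant-only letters (no
# vowels, no "s"/"y"): such words are fixed points of the stemmer and
# contain no digits, so the preprocessing pipeline passes them through
# unchanged and planted topic structure survives ingestion intact.
.syn_alphabet <- c("b", "c", "d", "f", "g", "h", "j", "k", "l", "m",
                   "n", "p", "q", "r", "t", "v", "w", "x", "z")

.syn_code <- function(i, width = 3L) {
  base <- length(.syn_alphabet)
  i <- i - 1L
  out <- character(width)
  for (pos in seq_len(width)) {
    out[[width - pos + 1L]] <- .syn_alphabet[(i %% base) + 1L]
    i <- i %/% base
  }
  paste(out, collapse = "")
}

.syn_vocab <- function(topic, n_tokens) {
  vapply(seq_len(n_tokens), function(v) {
    paste0(.syn_alphabet[[topic]], "q", .syn_code(v))
  }, character(1))
}

#' Configuration of the synthetic fixture
#'
#' Defines a corpus of `n_topics` planted topics with disjoint
#' per-topic vocabularies and an aligned gene-set collection with planted
#' overlaps and hub genes. One document is generated per gene set (set and
#' document ids coincide), so the corpus and the collection feed the full
#' pipeline end to end.
#'
#' @param n_topics Number of planted topics (default 4).
#' @param vocab_per_topic Tokens in each topic's vocabulary (default 50).
#' @param docs_per_topic Documents per topic (default 60).
#' @param doc_length Tokens per document (default 50).
#' @param sets_per_topic Gene sets per topic (default 60; equal to
#'   `docs_per_topic` for end-to-end runs).
#' @param genes_per_set Non-hub genes drawn per set (default 10).
#' @param overlap_fraction Expected pairwise overlap between same-topic
#'   sets, controlled through the per-topic gene-pool size
#'   `round(genes_per_set / overlap_fraction)` (default 0.1).
#' @param hub_genes_per_topic Hub genes inserted into every set of their
#'   topic (default 1; may be 0 for hub-free collections).
#' @param background_rate Fraction of each document's tokens drawn from a
#'   shared background vocabulary instead of the planted one (default 0).
#' @param seed Integer seed (default 1).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_topics = 4L, vocab_per_topic = 50L,
                             docs_per_topic = 60L, doc_length = 50L,
                             sets_per_topic = 60L, genes_per_set = 10L,
                             overlap_fraction = 0.1,
                             hub_genes_per_topic = 1L,
                             background_rate = 0, seed = 1L) {
  stopifnot(n_topics >= 1L, vocab_per_topic >= 1L, docs_per_topic >= 1L,
            doc_length >= 1L, sets_per_topic >= 1L, genes_per_set >= 1L,
            overlap_fraction >= 0, overlap_fraction <= 1,
            hub_genes_per_topic >= 0L,
            background_rate >= 0, background_rate <= 1,
            n_topics < length(.syn_alphabet))  # last letter is reserved for background tokens
  structure(
    list(n_topics = as.integer(n_topics),
         vocab_per_topic = as.integer(vocab_per_topic),
         docs_per_topic = as.integer(docs_per_topic),
         doc_length = as.integer(doc_length),
         sets_per_topic = as.integer(sets_per_topic),
         genes_per_set = as.integer(genes_per_set),
         overlap_fraction = overlap_fraction,
         hub_genes_per_topic = as.integer(hub_genes_per_topic),
         background_rate = background_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic corpus with planted topics
#'
#' Each planted topic owns a disjoint vocabulary of `vocab_per_topic`
#' tokens; each document samples `doc_length` tokens uniformly from its
#' topic's vocabulary, optionally mixed with a shared background vocabulary
#' at rate `background_rate`. Deterministic for a given seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `documents` (data frame `doc_id`, `set_id`, `source`,
#'   `text`) and `truth` (list with `doc_topics`, a named integer vector
#'   doc id -> planted topic, and `vocabularies`, per-topic token lists).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed, {
    vocabs <- lapply(seq_len(cfg$n_topics), .syn_vocab,
                     n_tokens = cfg$vocab_per_topic)
    background <- vapply(seq_len(cfg$vocab_per_topic), function(v) {
      paste0("zq", .syn_code(v))
    }, character(1))
    rows <- list()
    doc_topics <- integer(0)
    for (tp in seq_len(cfg$n_topics)) {
      for (d in seq_len(cfg$docs_per_topic)) {
        n_bg <- stats::rbinom(1L, cfg$doc_length, cfg$background_rate)
        toks <- c(
          sample(vocabs[[tp]], cfg$doc_length - n_bg, replace = TRUE),
          if (n_bg > 0L) sample(background, n_bg, replace = TRUE)
        )
        id <- sprintf("T%02dS%03d", tp, d)
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = id, set_id = id, source = "abstract",
          text = paste(toks, collapse = " "), stringsAsFactors = FALSE
        )
        doc_topics[[id]] <- tp
      }
    }
    list(
      documents = do.call(rbind, rows),
      truth = list(doc_topics = doc_topics, vocabularies = vocabs,
                   background = background)
    )
  })
}

#' Generate a synthetic gene-set collection with planted hubs
#'
#' Each topic owns a disjoint gene pool of size
#' `round(genes_per_set / overlap_fraction)` (so two same-topic sets share
#' `overlap_fraction * genes_per_set` genes in expectation). Every set
#' draws `genes_per_set` pool genes without replacement, and each planted
#' hub gene is inserted into all sets of its topic, making it the
#' best-connected gene of the topic's co-occurrence network. Set ids match
#' the document ids of [generate_corpus()] under the same configuration.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `sets` (named list of gene vectors with a
#'   `"description"` attribute) and `truth` (list with `set_topics`, named
#'   integer vector set id -> topic, and `hubs`, per-topic character
#'   vectors of hub genes).
#' @export
generate_genesets <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed + 1L, {
    pool_size <- if (cfg$overlap_fraction > 0) {
      max(cfg$genes_per_set, as.integer(round(cfg$genes_per_set /
                                                cfg$overlap_fraction)))
    } else {
      # pool large enough that sampled sets are almost surely disjoint
      cfg$genes_per_set * cfg$sets_per_topic * 50L
    }
    sets <- list()
    set_topics <- integer(0)
    hubs <- vector("list", cfg$n_topics)
    for (tp in seq_len(cfg$n_topics)) {
      pool <- sprintf("GENE_T%02d_%04d", tp, seq_len(pool_size))
      hubs[[tp]] <- sprintf("HUB_T%02d_%d", tp,
                            seq_len(cfg$hub_genes_per_topic))
      for (s in seq_len(cfg$sets_per_topic)) {
        id <- sprintf("T%02dS%03d", tp, s)
        sets[[id]] <- c(hubs[[tp]],
                        sample(pool, min(cfg$genes_per_set, pool_size)))
        set_topics[[id]] <- tp
      }
    }
    attr(sets, "description") <- stats::setNames(
      sprintf("synthetic set (planted topic %d)", set_topics), names(sets)
    )
    list(sets = sets,
         truth = list(set_topics = set_topics, hubs = hubs))
  })
}

#' Deterministic benchmark graphs
#'
#' Named small graphs used as oracle fixtures: `path(n)`, `cycle(n)`,
#' `star(n)` (n nodes, center first), `complete(n)`, `grid(nrow, ncol)`,
#' `two_triangles` (two disjoint triangles), `k_ary_tree(k, depth)`
#' (balanced tree; `depth` edges from root to leaf).
#'
#' @param name One of `"path"`, `"cycle"`, `"star"`, `"complete"`,
#'   `"grid"`, `"two_triangles"`, `"k_ary_tree"`.
#' @param n Node count for `path`, `cycle`, `star`, `complete`.
#' @param nrow,ncol Lattice dimensions for `grid`.
#' @param k,depth Branching factor and depth for `k_ary_tree`.
#' @return A `topic_network` with nodes named `v001`, `v002`, ...
#' @export
generate_benchmark_graph <- function(name, n = 5L, nrow = 3L, ncol = 3L,
                                     k = 2L, depth = 3L) {
  g <- switch(
    name,
    path = igraph::make_ring(n, circular = FALSE),
    cycle = igraph::make_ring(n, circular = TRUE),
    star = igraph::make_star(n, mode = "undirected", center = 1L),
    complete = igraph::make_full_graph(n),
    grid = igraph::make_lattice(c(nrow, ncol), periodic = FALSE),
    two_triangles = igraph::disjoint_union(igraph::make_full_graph(3L),
                                           igraph::make_full_graph(3L)),
    k_ary_tree = igraph::make_tree((k^(depth + 1L) - 1L) %/% (k - 1L),
                                   children = k, mode = "undirected"),
    stop("unknown benchmark graph: ", name)
  )
  igraph::V(g)$name <- sprintf("v%03d", seq_len(igraph::vcount(g)))
  structure(list(topic = NA_integer_, graph = g, provenance = character(0)),
            class = "topic_network")
}

#' Write the synthetic fixture to files
#'
#' Writes the gene-set collection (GMT), the document table (TSV), a small
#' default stopword list, and the planted ground truth (JSON) into a
#' directory, in exactly the formats the ingest functions read.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_synthetic_fixture <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_corpus(cfg)
  genes <- generate_genesets(cfg)
  paths <- c(
    gene_sets = file.path(dir, "gene_sets.gmt"),
    documents = file.path(dir, "documents.tsv"),
    stopwords = file.path(dir, "stopwords.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_gmt(genes$sets, paths[["gene_sets"]])
  write_documents(corpus$documents, paths[["documents"]])
  writeLines(c("# default stopword list", "the", "of", "and", "in", "to",
               "a", "is", "for", "with", "that"), paths[["stopwords"]])
  jsonlite::write_json(
    list(doc_topics = as.list(corpus$truth$doc_topics),
         set_topics = as.list(genes$truth$set_topics),
         hubs = genes$truth$hubs),
    paths[["truth"]], auto_unbox = TRUE
  )
  invisible(paths)
}
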