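# Full-pipeline orchestration: ingest -> topic model -> assignment ->
# per-topic networks -> graph/module/node analyses -> semantic map, with a
# JSON run manifest.

#' Pipeline configuration
#'
#' Bundles input paths and the analysis parameters. Defaults follow the
#' framework's standard settings: assignment threshold 0.2, 1000
#' perturbation iterations at rewiring rate 0.001, spectrum length 20, 100
#' top terms, rare-token cutoff 5.
#'
#' @param gene_sets Path to the gene-set GMT file.
#' @param documents Path to the document table (TSV or line-JSON).
#' @param out_dir Output directory.
#' @param stopwords Optional path to a stopword list.
#' @param annotations Optional path to an annotation GMT for module
#'   enrichment.
#' @param ontology_edges,ontology_annotations Optional paths to the term
#'   DAG edge table and term-annotation GMT for the semantic map.
#' @param k Number of topics; if `NULL`, selected over `k_grid`.
#' @param k_grid Candidate topic counts for selection (default `15:30`).
#' @param threshold Document-assignment confidence threshold (default 0.2).
#' @param multi_assign Assign documents to every topic above threshold
#'   (default `FALSE`).
#' @param min_freq Rare-token corpus-frequency cutoff (default 5).
#' @param lda_iter Gibbs sweeps (default 200).
#' @param perturb_iter,rewire_rate Perturbation iterations (default 1000)
#'   and per-iteration edge-rewiring rate (default 0.001).
#' @param spectrum_length Laplacian signature length (default 20).
#' @param top_terms Enriched terms per topic for the semantic map (default
#'   100).
#' @param seed Master seed; per-stage seeds are derived from it
#'   deterministically.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_sets, documents, out_dir,
                            stopwords = NULL, annotations = NULL,
                            ontology_edges = NULL,
                            ontology_annotations = NULL,
                            k = NULL, k_grid = 15:30, threshold = 0.2,
                            multi_assign = FALSE, min_freq = 5L,
                            lda_iter = 200L, perturb_iter = 1000L,
                            rewire_rate = 0.001, spectrum_length = 20L,
                            top_terms = 100L, seed = 1L) {
  structure(
    list(gene_sets = gene_sets, documents = documents, out_dir = out_dir,
         stopwords = stopwords, annotations = annotations,
         ontology_edges = ontology_edges,
         ontology_annotations = ontology_annotations,
         k = if (is.null(k)) NULL else as.integer(k),
         k_grid = as.integer(k_grid), threshold = threshold,
         multi_assign = isTRUE(multi_assign), min_freq = as.integer(min_freq),
         lda_iter = as.integer(lda_iter),
         perturb_iter = as.integer(perturb_iter), rewire_rate = rewire_rate,
         spectrum_length = as.integer(spectrum_length),
         top_terms = as.integer(top_terms), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# deterministic per-stage seeds below 2^31
.stage_seeds <- function(seed) {
  stages <- c("lda", "louvain", "perturb")
  stats::setNames(
    (as.numeric(seed) * 7919 + seq_along(stages) * 104729) %% 2147483647,
    stages
  )
}

.log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order and writes all outputs plus a
#' JSON manifest (parameters, seeds, per-stage row counts, produced files)
#' into `cfg$out_dir`. A rerun with the same configuration and seed
#' reproduces the outputs bit for bit. Topics that end up with fewer than
#' two assigned gene sets produce no network and are recorded as skipped;
#' the enrichment and semantic-map stages run only when their inputs are
#' configured (skipping is logged, not fatal).
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "networks"), showWarnings = FALSE)
  dir.create(file.path(out, "node_metrics"), showWarnings = FALSE)
  seeds <- .stage_seeds(cfg$seed)
  files <- character(0)
  counts <- list()

  ## ingest
  .log_stage("ingest", "reading gene sets and documents")
  sets <- tryCatch(read_gmt(cfg$gene_sets),
                   error = function(e) stop("stage ingest: ", conditionMessage(e)))
  docs <- tryCatch(read_documents(cfg$documents),
                   error = function(e) stop("stage ingest: ", conditionMessage(e)))
  stopw <- if (!is.null(cfg$stopwords)) {
    tryCatch(read_stopwords(cfg$stopwords),
             error = function(e) stop("stage ingest: ", conditionMessage(e)))
  } else character(0)
  merged <- merge_documents(docs)
  tokens <- lapply(stats::setNames(merged$text, merged$doc_id),
                   preprocess_text, stopwords = stopw)
  dtm <- build_dtm(tokens)
  dtm <- prune_rare_tokens(dtm, min_freq = cfg$min_freq)
  files <- c(files, write_dtm(dtm, file.path(out, "dtm")))
  counts$documents <- nrow(dtm)
  counts$vocabulary <- ncol(dtm)
  counts$gene_sets <- length(sets)

  ## topic model
  k <- cfg$k
  selection <- NULL
  if (is.null(k)) {
    .log_stage("fit-topics", "selecting k over grid of ",
               length(cfg$k_grid))
    selection <- select_k(dtm, k_grid = cfg$k_grid, seeds = seeds[["lda"]],
                          n_iter = cfg$lda_iter)
    k <- selection$chosen_k
    p <- file.path(out, "model_selection.json")
    jsonlite::write_json(selection[c("k_grid", "scores", "chosen_k")], p,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  .log_stage("fit-topics", "fitting LDA with k = ", k)
  model <- fit_topic_model(dtm, k = k, seed = seeds[["lda"]],
                           n_iter = cfg$lda_iter)
  files <- c(files, .write_tsv(
    data.frame(topic = rownames(model$beta), model$beta,
               check.names = FALSE), file.path(out, "beta.tsv")))
  files <- c(files, .write_tsv(
    data.frame(doc_id = rownames(model$gamma), model$gamma,
               check.names = FALSE), file.path(out, "gamma.tsv")))

  ## assignment
  .log_stage("assign", "threshold = ", cfg$threshold)
  assign_tab <- assign_documents(model, threshold = cfg$threshold,
                                 multi_assign = cfg$multi_assign)
  files <- c(files, .write_tsv(assign_tab, file.path(out, "assignments.tsv")))
  counts$assigned_documents <- sum(!is.na(assign_tab$topic))

  ## per-topic networks
  doc2set <- stats::setNames(docs$set_id[!duplicated(docs$doc_id)],
                             docs$doc_id[!duplicated(docs$doc_id)])
  topic_sets <- list()
  for (tp in seq_len(k)) {
    doc_ids <- assign_tab$doc_id[!is.na(assign_tab$topic) &
                                   assign_tab$topic == tp]
    sids <- unique(doc2set[doc_ids])
    sids <- sids[sids %in% names(sets)]
    topic_sets[[tp]] <- sids
  }
  networks <- list()
  skipped <- integer(0)
  for (tp in seq_len(k)) {
    sids <- topic_sets[[tp]]
    if (length(sids) < 2L) {
      .log_stage("build-networks", "topic ", tp,
                 " skipped (<2 assigned gene sets)")
      skipped <- c(skipped, tp)
      next
    }
    net <- build_topic_network(sets[sids], topic = tp)
    if (igraph::ecount(net$graph) == 0L) {
      .log_stage("build-networks", "topic ", tp,
                 " skipped (no co-occurring genes)")
      skipped <- c(skipped, tp)
      next
    }
    networks[[as.character(tp)]] <- net
    files <- c(files, write_network_edges(
      net, file.path(out, "networks", sprintf("topic_%02d_edges.tsv", tp))))
  }
  p <- file.path(out, "topics_manifest.json")
  jsonlite::write_json(
    list(k = k, topics = stats::setNames(topic_sets, seq_len(k)),
         skipped = skipped), p, auto_unbox = TRUE)
  files <- c(files, p)
  counts$networks <- length(networks)
  if (length(networks) == 0L) stop("stage build-networks: no topic network could be built")

  ## network-level metrics and spectra
  .log_stage("network-metrics", length(networks), " networks")
  gm <- do.call(rbind, lapply(networks, global_metrics,
                              louvain_seed = seeds[["louvain"]]))
  files <- c(files, .write_tsv(gm, file.path(out, "network_metrics.tsv")))
  sigs <- lapply(networks, laplacian_spectrum, m = cfg$spectrum_length)
  spec_mat <- do.call(rbind, lapply(sigs, function(s) s$eigenvalues))
  colnames(spec_mat) <- paste0("ev", seq_len(ncol(spec_mat)))
  spec_tab <- data.frame(
    topic = vapply(sigs, function(s) s$topic, integer(1)),
    spec_mat
  )
  files <- c(files, .write_tsv(spec_tab, file.path(out, "spectra.tsv")))
  dm <- spectral_distance_matrix(sigs)
  files <- c(files, .write_tsv(
    data.frame(topic = rownames(dm), dm, check.names = FALSE),
    file.path(out, "spectral_distances.tsv")))

  ## modules + enrichment
  .log_stage("modules", "Louvain partitions")
  partitions <- lapply(networks, louvain_partition, seed = seeds[["louvain"]])
  mod_assign <- do.call(rbind, lapply(partitions, function(p) {
    data.frame(gene = names(p$assignment), topic = p$topic,
               module = as.integer(p$assignment), stringsAsFactors = FALSE)
  }))
  files <- c(files, .write_tsv(mod_assign, file.path(out, "modules.tsv")))
  mm <- do.call(rbind, Map(module_metrics, networks, partitions))
  files <- c(files, .write_tsv(mm, file.path(out, "module_metrics.tsv")))

  enrich_tab <- NULL
  if (!is.null(cfg$annotations)) {
    .log_stage("enrich", "hypergeometric ORA")
    terms <- read_gmt(cfg$annotations)
    ann_genes <- unique(unlist(terms, use.names = FALSE))
    enr <- list()
    for (tp in names(networks)) {
      part <- partitions[[tp]]
      universe <- intersect(network_nodes(networks[[tp]]), ann_genes)
      if (length(universe) == 0L) next
      for (mod in sort(unique(part$assignment))) {
        mg <- names(part$assignment)[part$assignment == mod]
        tab <- hypergeometric_ora(mg, terms, universe)
        if (nrow(tab) > 0L) {
          tab <- cbind(data.frame(topic = as.integer(tp), module = mod), tab)
          enr[[length(enr) + 1L]] <- tab
        }
      }
    }
    enrich_tab <- if (length(enr) > 0L) do.call(rbind, enr) else NULL
    if (!is.null(enrich_tab)) {
      files <- c(files, .write_tsv(enrich_tab,
                                   file.path(out, "enrichment.tsv")))
    }
  } else {
    .log_stage("enrich", "skipped (no annotation collection configured)")
  }

  ## node-level metrics
  .log_stage("node-metrics", "centrality, LFD, perturbation variance")
  node_tabs <- list()
  for (tp in names(networks)) {
    cfg_pert <- perturbation_config(n_iter = cfg$perturb_iter,
                                    rewire_rate = cfg$rewire_rate,
                                    seed = seeds[["perturb"]] +
                                      as.integer(tp))
    tab <- node_metrics_table(networks[[tp]], perturb = cfg_pert)
    node_tabs[[tp]] <- tab
    files <- c(files, .write_tsv(
      tab, file.path(out, "node_metrics", sprintf("topic_%02d.tsv",
                                                  as.integer(tp)))))
  }
  long <- do.call(rbind, node_tabs)
  files <- c(files, .write_tsv(long, file.path(out, "node_metrics_long.tsv")))
  counts$genes_scored <- nrow(long)

  ## semantic map
  if (!is.null(cfg$ontology_edges) && !is.null(cfg$ontology_annotations) &&
      !is.null(enrich_tab)) {
    .log_stage("semantic-map", "Lin similarity + classical MDS")
    dag <- read_ontology(cfg$ontology_edges, cfg$ontology_annotations)
    topic_terms <- list()
    for (tp in unique(enrich_tab$topic)) {
      rows <- enrich_tab[enrich_tab$topic == tp, , drop = FALSE]
      sel <- select_top_terms(rows, n = cfg$top_terms)
      sel <- intersect(sel, dag$terms)
      if (length(sel) > 0L) topic_terms[[as.character(tp)]] <- sel
    }
    all_terms <- unique(unlist(topic_terms, use.names = FALSE))
    if (length(all_terms) >= 2L) {
      sim <- term_similarity_matrix(all_terms, dag)
      coords <- classical_mds(sim, dims = 2L)
      files <- c(files, .write_tsv(
        data.frame(term_id = rownames(coords), coords, check.names = FALSE),
        file.path(out, "term_coordinates.tsv")))
      centroids <- topic_centroids(coords, topic_terms)
      files <- c(files, .write_tsv(centroids,
                                   file.path(out, "topic_centroids.tsv")))
    } else {
      .log_stage("semantic-map", "skipped (fewer than 2 mappable terms)")
    }
  } else {
    .log_stage("semantic-map", "skipped (no ontology configured)")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("topicnets")),
    parameters = cfg[setdiff(names(cfg), c())],
    seeds = as.list(seeds),
    k = k,
    counts = counts,
    skipped_topics = skipped,
    files = vapply(unname(files), function(f) {
      sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out), "/?"),
          "", f)
    }, character(1))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
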