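# Topic modeling: seeded collapsed-Gibbs LDA, Jensen-Shannon topic-count
# selection, and thresholded document-to-topic assignment.

#' Fit a latent Dirichlet allocation topic model
#'
#' Fits LDA to a pruned document-term matrix with a collapsed Gibbs sampler.
#' Topic-term (`beta`, k x V) and document-topic (`gamma`, D x k)
#' distributions are the smoothed estimates from the final sampler state:
#' `beta[k, v] = (n_kv + eta) / (n_k + V * eta)` and
#' `gamma[d, k] = (n_dk + alpha) / (n_d + K * alpha)`.
#' The same `(dtm, k, seed, hyperparameters)` always reproduces the same fit
#' bit for bit.
#'
#' @param dtm Document-term count matrix (documents x tokens), typically
#'   from [prune_rare_tokens()]; no document row may be all zero.
#' @param k Number of topics (>= 2, <= number of documents).
#' @param seed Integer seed for the sampler.
#' @param alpha Dirichlet prior on document-topic weights (default `50 / k`).
#' @param eta Dirichlet prior on topic-term weights (default 0.1).
#' @param n_iter Gibbs sweeps over the corpus (default 200).
#' @return An object of class `topic_model`: list with elements `k`, `beta`,
#'   `gamma`, `seed`, `alpha`, `eta`, `n_iter`.
#' @export
fit_topic_model <- function(dtm, k, seed = 1L, alpha = 50 / k, eta = 0.1,
                            n_iter = 200L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(dtm)) {
    stop("k (", k, ") exceeds the number of documents (", nrow(dtm), ")")
  }
  if (any(Matrix::rowSums(dtm) == 0)) {
    stop("document-term matrix contains empty documents; prune first")
  }
  stopifnot(alpha > 0, eta > 0, n_iter >= 1L)

  trip <- methods::as(methods::as(dtm, "CsparseMatrix"), "TsparseMatrix")
  ord <- order(trip@i, trip@j)
  di <- trip@i[ord]
  wj <- trip@j[ord]
  cnt <- as.integer(trip@x[ord])
  doc <- rep.int(di, cnt)
  word <- rep.int(wj, cnt)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  counts <- .gibbs_lda_cpp(doc, word, nrow(dtm), ncol(dtm), k,
                           alpha, eta, as.integer(n_iter))

  beta <- (counts$nkv + eta) / (counts$nk + ncol(dtm) * eta)
  nd <- Matrix::rowSums(dtm)
  gamma <- (counts$ndk + alpha) / (nd + k * alpha)
  dimnames(beta) <- list(paste0("topic_", seq_len(k)), colnames(dtm))
  dimnames(gamma) <- list(rownames(dtm), paste0("topic_", seq_len(k)))

  structure(
    list(k = k, beta = beta, gamma = gamma, seed = as.integer(seed),
         alpha = alpha, eta = eta, n_iter = as.integer(n_iter)),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat("LDA topic model: k =", x$k, ", D =", nrow(x$gamma),
      ", V =", ncol(x$beta), "\n")
  cat("  seed =", x$seed, ", alpha =", signif(x$alpha, 4),
      ", eta =", signif(x$eta, 4), ", sweeps =", x$n_iter, "\n")
  invisible(x)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, natural
#' logarithm, and `0 * log 0 = 0`; bounded by `log(2)`.
#'
#' @param p,q Probability vectors of equal length, each summing to 1.
#' @return The divergence, a scalar in `[0, log(2)]`.
#' @export
jensen_shannon_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("p and q must each sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log(a[nz]) - log(b[nz])))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Mean pairwise topic divergence of a fitted model
#'
#' Scores topic separation as the mean Jensen-Shannon divergence over all
#' pairs of distinct topic-term distributions (rows of `beta`). Larger
#' means better-separated topics; used as the topic-count selection
#' criterion.
#'
#' @param model A `topic_model`.
#' @return Mean pairwise divergence, in `[0, log(2)]`.
#' @export
deveaud_score <- function(model) {
  stopifnot(inherits(model, "topic_model"))
  k <- model$k
  if (k < 2L) stop("k must be >= 2")
  tot <- 0
  npair <- 0L
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      tot <- tot + jensen_shannon_divergence(model$beta[a, ], model$beta[b, ])
      npair <- npair + 1L
    }
  }
  tot / npair
}

#' Select the number of topics by mean pairwise divergence
#'
#' Fits a model for every `k` in `k_grid` (for each seed in `seeds`), scores
#' each fit with [deveaud_score()], averages scores over seeds, and picks
#' the `k` with the highest mean score (ties go to the smallest `k`).
#'
#' @param dtm Pruned document-term matrix.
#' @param k_grid Integer vector of candidate topic counts (default `15:30`).
#' @param seeds Integer vector of seeds to average over (default `1`).
#' @param ... Further arguments passed to [fit_topic_model()].
#' @return An object of class `model_selection_report`: list with `k_grid`,
#'   `scores` (mean per k), `chosen_k`, `seeds`.
#' @export
select_k <- function(dtm, k_grid = 15:30, seeds = 1L, ...) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0L) stop("k_grid must be non-empty")
  scores <- vapply(k_grid, function(k) {
    mean(vapply(seeds, function(s) {
      deveaud_score(fit_topic_model(dtm, k = k, seed = s, ...))
    }, numeric(1)))
  }, numeric(1))
  chosen <- k_grid[which.max(scores)]  # which.max takes the first (smallest k)
  structure(
    list(k_grid = k_grid, scores = scores, chosen_k = chosen,
         seeds = as.integer(seeds)),
    class = "model_selection_report"
  )
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat("Topic-count selection over k in {", paste(x$k_grid, collapse = ", "),
      "}\n")
  cat("  chosen k =", x$chosen_k, "(max mean pairwise divergence",
      signif(max(x$scores), 4), ")\n")
  invisible(x)
}

#' Assign documents to topics with a confidence threshold
#'
#' Each document's confidence is the maximum of its document-topic weights
#' (`gamma` row); the document is assigned to the arg-max topic if the
#' confidence reaches `threshold`, otherwise left unassigned. Arg-max ties
#' break to the smallest topic index. With `multi_assign = TRUE` a document
#' is instead assigned to every topic whose weight reaches the threshold.
#'
#' @param model A `topic_model`.
#' @param threshold Minimum posterior weight for assignment, in `(0, 1]`
#'   (default 0.2).
#' @param multi_assign Assign to all topics above threshold instead of only
#'   the arg max (default `FALSE`).
#' @return Data frame with columns `doc_id`, `topic` (integer, `NA` when
#'   unassigned), `confidence`. With `multi_assign` a document may occupy
#'   several rows (one per qualifying topic).
#' @export
assign_documents <- function(model, threshold = 0.2, multi_assign = FALSE) {
  stopifnot(inherits(model, "topic_model"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  gamma <- model$gamma
  doc_ids <- rownames(gamma)
  if (multi_assign) {
    rows <- lapply(seq_len(nrow(gamma)), function(d) {
      hits <- which(gamma[d, ] >= threshold)
      if (length(hits) == 0L) {
        data.frame(doc_id = doc_ids[d], topic = NA_integer_,
                   confidence = max(gamma[d, ]), stringsAsFactors = FALSE)
      } else {
        data.frame(doc_id = doc_ids[d], topic = as.integer(hits),
                   confidence = as.numeric(gamma[d, hits]),
                   stringsAsFactors = FALSE)
      }
    })
    return(do.call(rbind, rows))
  }
  conf <- apply(gamma, 1L, max)
  top <- apply(gamma, 1L, which.max)  # first index on ties
  data.frame(
    doc_id = doc_ids,
    topic = ifelse(conf >= threshold, as.integer(top), NA_integer_),
    confidence = as.numeric(conf),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
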