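# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph, where igraph is the implementation).

# ---- brute-force betweenness: enumerate every simple path per pair -------
# adj: symmetric logical/0-1 matrix. Returns unnormalized betweenness with
# each unordered pair counted once.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  enum_paths <- function(cur, target, visited) {
    if (cur == target) return(list(visited))
    out <- list()
    for (nb in which(adj[cur, ] > 0)) {
      if (!(nb %in% visited)) {
        out <- c(out, enum_paths(nb, target, c(visited, nb)))
      }
    }
    out
  }
  if (n < 2) return(btw)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enum_paths(s, t, s)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / sigma
      }
    }
  }
  btw
}

# ---- dense eigendecomposition oracle for eigenvector centrality ----------
oracle_eigenvector <- function(adj) {
  e <- eigen(adj, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / max(v)
}

# ---- double-loop clique-union oracle for network construction ------------
# Returns a sorted character vector of canonical "a|b" edge keys.
oracle_cooccurrence_edges <- function(sets) {
  keys <- character(0)
  n <- length(sets)
  if (n >= 2) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        inter <- intersect(unique(sets[[s]]), unique(sets[[t]]))
        if (length(inter) < 2) next
        for (a in seq_along(inter)) {
          for (b in seq_along(inter)) {
            if (a < b) {
              pair <- sort(c(inter[[a]], inter[[b]]), method = "radix")
              keys <- c(keys, paste(pair, collapse = "|"))
            }
          }
        }
      }
    }
  }
  sort(unique(keys), method = "radix")
}

edge_keys <- function(net) {
  el <- network_edges(net)
  if (nrow(el) == 0) return(character(0))
  keys <- apply(el, 1, function(e) {
    paste(sort(e, method = "radix"), collapse = "|")
  })
  sort(keys, method = "radix")
}

# ---- direct-summation Jensen-Shannon oracle ------------------------------
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) total <- total + 0.5 * p[i] * log(p[i] / m[i])
    if (q[i] > 0) total <- total + 0.5 * q[i] * log(q[i] / m[i])
  }
  total
}

# ---- exhaustive hypergeometric enumeration -------------------------------
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  js <- k:hi
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# ---- literal step-up Benjamini-Hochberg ----------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# ---- least-squares slope oracle ------------------------------------------
oracle_slope <- function(x, y) {
  unname(stats::coef(stats::lm(y ~ x))[2])
}

# ---- random graphs / collections -----------------------------------------
random_connected_adj <- function(n) {
  repeat {
    adj <- matrix(0L, n, n)
    upper <- which(upper.tri(adj))
    on <- upper[stats::runif(length(upper)) < stats::runif(1, 0.3, 0.9)]
    adj[on] <- 1L
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    # BFS connectivity check (no igraph)
    seen <- c(1L)
    frontier <- c(1L)
    while (length(frontier) > 0) {
      nxt <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) == n) return(adj)
  }
}

adj_to_network <- function(adj, names = sprintf("n%02d", seq_len(nrow(adj)))) {
  idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  el <- cbind(names[idx[, 1]], names[idx[, 2]])
  topic_network(el)
}

random_geneset_collection <- function(max_sets = 10, max_genes = 20) {
  n_sets <- sample(2:max_sets, 1)
  pool <- paste0("g", seq_len(max_genes))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(pool, sample(2:max_genes, 1))
  })
  names(sets) <- paste0("S", seq_len(n_sets))
  sets
}

# ---- optimal topic-to-label matching accuracy ----------------------------
match_accuracy <- function(pred, truth, k) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (perm in perms(seq_len(k))) {
    hit <- perm[pred] == truth
    hit[is.na(hit)] <- FALSE  # unassigned documents count as misses
    best <- max(best, mean(hit))
  }
  best
}
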