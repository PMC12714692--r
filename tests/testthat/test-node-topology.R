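# Node-level metrics: centralities, local fractal dimension, perturbation
# variance, rescaling, gene-set aggregation.

test_that("betweenness matches closed forms and path enumeration", {
  k4 <- generate_benchmark_graph("complete", n = 4)
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))

  star5 <- generate_benchmark_graph("star", n = 5)
  b <- betweenness_centrality(star5)
  expect_equal(unname(b[order(-b)]), c(choose(4, 2), 0, 0, 0, 0))

  p4 <- generate_benchmark_graph("path", n = 4)
  adj <- as.matrix(igraph::as_adjacency_matrix(p4$graph))
  expect_equal(unname(betweenness_centrality(p4)), oracle_betweenness(adj),
               tolerance = 1e-12)
  expect_equal(unname(betweenness_centrality(p4)), c(0, 2, 2, 0))
})

test_that("eigenvector centrality matches dense eigendecompositions", {
  k4 <- generate_benchmark_graph("complete", n = 4)
  expect_equal(unname(eigenvector_centrality(k4)), rep(1, 4),
               tolerance = 1e-9)

  p3 <- generate_benchmark_graph("path", n = 3)
  ev <- eigenvector_centrality(p3, tol = 1e-12)
  expect_equal(unname(ev), c(1 / sqrt(2), 1, 1 / sqrt(2)), tolerance = 1e-9)

  star6 <- generate_benchmark_graph("star", n = 6)
  ev_s <- eigenvector_centrality(star6, tol = 1e-12)
  expect_equal(unname(ev_s[order(-ev_s)]),
               c(1, rep(1 / sqrt(5), 5)), tolerance = 1e-9)

  expect_error(eigenvector_centrality(p3, tol = 0, max_iter = 3),
               "max_iter = 3")
})

test_that("local fractal dimension follows the log-log ball growth", {
  # quoted neighborhood profile: 2, 29, 373 nodes within 1, 2, 3 steps
  counts <- c(2, 29, 373)
  expect_equal(lfd_from_counts(counts),
               oracle_slope(log(1:3), log(counts)), tolerance = 1e-12)

  # a star leaf sees 1 node at r=1 and n-1 at r=2: two-point slope
  star8 <- generate_benchmark_graph("star", n = 8)
  leaf <- network_nodes(star8)[2]
  expect_equal(local_fractal_dimension(star8, leaf), log(7) / log(2),
               tolerance = 1e-12)

  # eccentricity < 2 leaves fewer than two radii: LFD 0
  k5 <- generate_benchmark_graph("complete", n = 5)
  expect_equal(local_fractal_dimension(k5, "v001"), 0)

  # invariant under node relabeling
  g1 <- generate_benchmark_graph("grid", nrow = 3, ncol = 4)
  el <- network_edges(g1)
  relabel <- stats::setNames(paste0("X", seq_along(network_nodes(g1))),
                             network_nodes(g1))
  g2 <- topic_network(cbind(relabel[el[, 1]], relabel[el[, 2]]))
  expect_equal(local_fractal_dimension(g1, "v001"),
               local_fractal_dimension(g2, relabel[["v001"]]))

  # the center of a balanced k-ary tree grows denser with k
  lfd_center <- vapply(2:4, function(k) {
    tree <- generate_benchmark_graph("k_ary_tree", k = k, depth = 5)
    local_fractal_dimension(tree, "v001")
  }, numeric(1))
  expect_true(all(diff(lfd_center) >= 0))

  expect_error(local_fractal_dimension(k5, "nope"), "not in network")
})

test_that("perturbation preserves structure and is seed-reproducible", {
  net <- generate_benchmark_graph("grid", nrow = 3, ncol = 4)
  cfg <- perturbation_config(n_iter = 25, rewire_rate = 0.001, seed = 42)
  det <- perturb_and_score(net, cfg, detail = TRUE)

  # node set and edge count preserved in every iteration
  expect_equal(det$n_edges, rep(igraph::ecount(net$graph), 25))
  expect_equal(rownames(det$betweenness), network_nodes(net))
  expect_equal(det$n_rewired, 1)  # round(0.001 * 17) = 0 -> floor of 1

  # bit-identical rerun under the same seed
  det2 <- perturb_and_score(net, cfg, detail = TRUE)
  expect_identical(det$betweenness, det2$betweenness)
  expect_identical(det$variance, det2$variance)

  # complete graph: the removed edge is the only reinsertion candidate,
  # so every iteration restores the original graph
  k5 <- generate_benchmark_graph("complete", n = 5)
  v <- perturb_and_score(k5, perturbation_config(n_iter = 10, seed = 1))
  expect_equal(unname(v), rep(0, 5))

  expect_error(
    perturb_and_score(topic_network(matrix(character(0), 0, 2)),
                      perturbation_config(n_iter = 2)),
    "no edges"
  )
})

test_that("perturbation variance equals a literal re-run of the procedure", {
  net <- topic_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                             c("d", "e"), c("e", "f"), c("b", "e")))
  cfg <- perturbation_config(n_iter = 3, rewire_rate = 0.001, seed = 99)
  got <- perturb_and_score(net, cfg)

  # independent implementation of the documented procedure, consuming the
  # RNG in the documented order (edge draw, then candidate-pair draws)
  g0 <- net$graph
  n <- igraph::vcount(g0)
  el0 <- igraph::as_edgelist(g0, names = FALSE)
  set.seed(99)
  btw <- matrix(NA_real_, n, 3)
  for (it in 1:3) {
    el <- el0
    adj <- matrix(FALSE, n, n)
    adj[el0] <- TRUE
    adj[el0[, 2:1]] <- TRUE
    e <- sample.int(nrow(el), 1)
    adj[el[e, 1], el[e, 2]] <- FALSE
    adj[el[e, 2], el[e, 1]] <- FALSE
    repeat {
      i <- sample.int(n, 1)
      j <- sample.int(n, 1)
      if (i != j && !adj[i, j]) break
    }
    el[e, ] <- c(i, j)
    gi <- igraph::make_graph(as.vector(t(el)), n = n, directed = FALSE)
    btw[, it] <- igraph::betweenness(gi, directed = FALSE)
  }
  manual_var <- rowMeans((btw - rowMeans(btw))^2)
  expect_equal(unname(got), manual_var, tolerance = 1e-12)
})

test_that("rescale_unit_interval is a monotone affine-invariant map", {
  expect_equal(unname(rescale_unit_interval(c(1, 3, 5))), c(0, 0.5, 1))
  expect_equal(unname(rescale_unit_interval(c(2, 2, 2))), rep(0.5, 3))

  set.seed(5)
  x <- stats::setNames(stats::rnorm(20), paste0("g", 1:20))
  y <- rescale_unit_interval(x)
  expect_equal(unname(stats::cor(x, y, method = "spearman")), 1)
  expect_equal(rescale_unit_interval(3 * x + 7), y)  # affine invariance
  expect_true(all(y >= 0 & y <= 1))

  open <- rescale_unit_interval(x, open = TRUE)
  expect_true(all(open > 0 & open < 1))
})

test_that("node_metrics_table scores every node with bounded columns", {
  net <- generate_benchmark_graph("grid", nrow = 3, ncol = 3)
  tab <- node_metrics_table(net, perturb = perturbation_config(n_iter = 10,
                                                               seed = 2))
  expect_equal(nrow(tab), igraph::vcount(net$graph))
  expect_setequal(tab$gene, network_nodes(net))
  scaled <- c("betweenness_scaled", "eigenvector_scaled", "lfd_scaled",
              "btw_variance_scaled")
  for (col in scaled) {
    expect_true(all(tab[[col]] >= 0 & tab[[col]] <= 1))
  }
  expect_true(all(tab$betweenness_raw >= 0))
  expect_true(all(tab$btw_variance_raw >= 0))
})

test_that("geneset_topology_score averages the rescaled metric overlap", {
  net <- generate_benchmark_graph("grid", nrow = 3, ncol = 3)
  tab <- node_metrics_table(net, perturb = perturbation_config(n_iter = 5,
                                                               seed = 3))
  one <- geneset_topology_score(tab, "v001", metric = "betweenness_scaled")
  expect_equal(one$score,
               tab$betweenness_scaled[tab$gene == "v001"])
  expect_equal(one$n_overlap, 1L)

  off <- geneset_topology_score(tab, c("nope1", "nope2"))
  expect_false(off$defined)
  expect_equal(off$coverage, 0)
  expect_true(is.na(off$score))

  five <- c("v001", "v002", "v003", "v004", "v005")
  sc <- geneset_topology_score(tab, c(five, "offgrid"),
                               metric = "eigenvector_scaled")
  expect_equal(sc$score,
               mean(tab$eigenvector_scaled[match(five, tab$gene)]))
  expect_equal(sc$coverage, 5 / 9)
})
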