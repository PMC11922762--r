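test_that("kNN graph matches hand geometry and tie-break contracts", {
  # collinear points at 0, 1, 3 with k = 1: union symmetrization keeps B-C
  s <- matrix(c(0, 1, 3), 3, 1, dimnames = list(c("A", "B", "C"), "PC1"))
  g <- knn_graph(s, k = 1)
  expect_true(g$adj["A", "B"] && g$adj["B", "C"])
  expect_false(g$adj["A", "C"])
  expect_equal(sum(g$adj) / 2, 2)

  # all points identical: k nearest are the lexicographically smallest ids
  s2 <- matrix(0, 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  g2 <- knn_graph(s2, k = 2)
  # a,b,c link among themselves; d links to a,b; union adds nothing for c-d
  expect_true(all(g2$adj["d", c("a", "b")]))
  expect_false(g2$adj["d", "c"])
  expect_true(g2$adj["b", "c"])     # from c's side via symmetrization

  expect_error(knn_graph(s2, k = 4), "smaller")
})

test_that("well-separated blobs produce no cross-blob edges", {
  set.seed(1)
  s <- rbind(matrix(rnorm(30 * 3), 30, 3),
             matrix(rnorm(30 * 3, mean = 30), 30, 3))
  rownames(s) <- sprintf("s%02d", 1:60)
  g <- knn_graph(s, k = 5)
  cross <- g$adj[1:30, 31:60]
  expect_equal(sum(cross), 0)
})

test_that("modularity matches closed forms and the igraph oracle", {
  cl2 <- disjoint_cliques(2, 3)
  g <- as_graph(cl2)
  lab <- rep(1:2, each = 3)
  expect_equal(modularity_q(g, lab), 0.5)
  expect_equal(modularity_q(g, rep(1, 6)), 0)
  # random labels on an Erdos-Renyi graph are centred on ~0 (the exact
  # expectation is -(2/3) sum(d^2)/(2m)^2, vanishing with graph size)
  set.seed(2)
  adj <- random_adjacency(100, 0.3)
  gg <- as_graph(adj)
  qs <- replicate(100, modularity_q(gg, sample(1:3, 100, TRUE)))
  expect_lt(abs(mean(qs)), 0.02)
  adj <- random_adjacency(30, 0.2)
  gg <- as_graph(adj)
  # against the independent oracle and igraph on random labellings
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  for (i in 1:20) {
    lab <- sample(1:4, 30, TRUE)
    expect_equal(modularity_q(gg, lab), oracle_modularity(adj, lab),
                 tolerance = 1e-12)
    expect_equal(modularity_q(gg, lab), igraph::modularity(ig, lab),
                 tolerance = 1e-12)
  }
})

test_that("Louvain solves the clique benchmarks", {
  g <- as_graph(disjoint_cliques(2, 3))
  cl <- louvain(g, seed = 0)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(cl$Q, 0.5)
  # complete graph: the trivial partition, never Q < 0
  k6 <- matrix(1, 6, 6); diag(k6) <- 0
  dimnames(k6) <- list(letters[1:6], letters[1:6])
  cl6 <- louvain(as_graph(k6), seed = 0)
  expect_equal(length(unique(cl6$labels)), 1)
  expect_equal(cl6$Q, 0)
})

test_that("Louvain restarts match the reference implementation graph by graph", {
  # greedy modularity optimization is basin-dependent; what a correct
  # implementation must deliver is the reference algorithm's quality.
  # Compare best-of-20 seeded restarts against igraph's multilevel
  # algorithm (best of 20 randomized runs) on independent small graphs.
  skip_if_not_installed("igraph")
  set.seed(3)
  graphs <- list()
  for (i in 1:20) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, 0.5)
    if (sum(adj) > 0) graphs[[length(graphs) + 1]] <- adj
  }
  for (i in seq_along(graphs)) {
    adj <- graphs[[i]]
    cl <- louvain(as_graph(adj), seed = i, n_restarts = 20)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    set.seed(i)
    qig <- max(replicate(20, igraph::modularity(
      ig, igraph::membership(igraph::cluster_louvain(ig)))))
    expect_gte(cl$Q, qig - 0.02)
  }
})

test_that("the move phase never decreases Q and the final Q is re-derivable", {
  set.seed(4)
  for (i in 1:5) {
    adj <- random_adjacency(40, 0.15)
    g <- as_graph(adj)
    cl <- louvain(g, seed = i)
    expect_true(all(diff(cl$q_trace) >= -1e-12))
    expect_equal(cl$Q, modularity_q(g, cl$labels), tolerance = 1e-10)
    expect_equal(cl$Q, oracle_modularity(adj, cl$labels), tolerance = 1e-10)
  }
})

test_that("Louvain reaches comparable modularity to igraph's implementation", {
  skip_if_not_installed("igraph")
  set.seed(5)
  adj <- random_adjacency(60, 0.1)
  g <- as_graph(adj)
  cl <- louvain(g, seed = 0, n_restarts = 3)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  qi <- igraph::modularity(ig, igraph::membership(igraph::cluster_louvain(ig)))
  expect_gte(cl$Q, qi - 0.02)
})

test_that("cluster labels are ordered by human sample count, deterministically", {
  adj <- disjoint_cliques(2, 4)        # two components of 4 nodes
  sp <- c(rep("mouse", 4), rep("human", 4))
  g <- as_graph(adj, species = sp)
  cl <- louvain(g, seed = 0)
  # the all-human clique must be cluster 1
  expect_true(all(cl$labels[5:8] == 1))
  expect_true(all(cl$labels[1:4] == 2))
  # ties (no species info) fall back to size then smallest member id
  g2 <- as_graph(disjoint_cliques(2, 3))
  cl2 <- louvain(g2, seed = 0)
  expect_equal(unname(cl2$labels[1]), 1)   # component containing "a"
})

test_that("nearest-reference classification honours degenerate distances", {
  set.seed(6)
  s_ref <- rbind(matrix(rnorm(20 * 4), 20, 4),
                 matrix(rnorm(20 * 4, 10), 20, 4))
  rownames(s_ref) <- sprintf("r%02d", 1:40)
  lab <- setNames(rep(1:2, each = 20), rownames(s_ref))
  s_new <- s_ref[c(3, 25), , drop = FALSE]
  rownames(s_new) <- c("n1", "n2")
  cl <- classify_new(s_new, s_ref, lab, mode = "nearest_reference",
                     k_vote = 1)
  expect_equal(unname(cl$labels), c(1, 2))
})

test_that("joint-mode reclassification of the reference is self-consistent", {
  skip_if_not_installed("mclust")
  set.seed(7)
  s_ref <- rbind(matrix(rnorm(25 * 5), 25, 5),
                 matrix(rnorm(25 * 5, 12), 25, 5),
                 matrix(rnorm(25 * 5, -12), 25, 5))
  rownames(s_ref) <- sprintf("r%02d", 1:75)
  ref_cl <- louvain(knn_graph(s_ref, k = 8), seed = 0)
  s_new <- s_ref
  rownames(s_new) <- sprintf("v%02d", 1:75)
  cl <- classify_new(s_new, s_ref, ref_cl, mode = "joint", k = 8, seed = 0)
  expect_equal(mclust::adjustedRandIndex(cl$labels, ref_cl$labels), 1)
})

test_that("held-out samples are recovered at strong effect", {
  sim <- simulate_cohort(n_genes = 300, n_orthologs = 250, n_human = 90,
                         n_mouse = 30, k_true = 4, frac_marker = 0.15,
                         log2_effect = 1.5, seed = 8)
  train <- sim$human_counts[, 1:60]
  test <- sim$human_counts[, 61:90]
  fit <- humo_fit(train, sim$mouse_counts, sim$ortholog_map, rank = 15,
                  knn_k = 10, seed = 0, umap = FALSE)
  truth <- sim$true_labels
  map <- cluster_to_truth_map(fit$clusters$labels,
                              truth[names(fit$clusters$labels)])
  pred <- predict(fit, test, mode = "nearest_reference")
  agree <- mean(map[as.character(pred$labels)] ==
                truth[names(pred$labels)])
  expect_gte(agree, 0.9)
})

test_that("space mismatch between score matrices is a hard error", {
  e1 <- center_within_sample(matrix(rnorm(100 * 10), 100, 10,
        dimnames = list(paste0("g", 1:100), paste0("s", 1:10))))
  e2 <- center_within_sample(matrix(rnorm(100 * 10), 100, 10,
        dimnames = list(paste0("h", 1:100), paste0("t", 1:10))))
  sp1 <- fit_human_space(e1, 3)
  sp2 <- fit_human_space(e2, 3)
  s1 <- project_scores(e1, sp1)
  s2 <- project_scores(e2, sp2)
  lab <- setNames(rep(1, 10), rownames(s1))
  expect_error(classify_new(s2, s1, lab), "different embedding spaces")
  expect_error(bind_scores(s1, s2), "different embedding spaces")
})
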