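# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives its quantity from first principles, separately
# from the package's implementation path.

# two-sided Fisher p by direct hypergeometric enumeration of all tables
# with the observed margins, summing probabilities <= observed (with a
# relative tolerance for floating-point ties)
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])                # feature-positive margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])                # group margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# direct two-loop evaluation of the ssGSEA running-sum statistic
oracle_ssgsea <- function(x, gene_set, alpha) {
  genes <- names(x)
  ord <- order(-x, genes)
  xo <- x[ord]
  go <- genes[ord]
  inset <- go %in% gene_set
  N <- length(x)
  ng <- sum(inset)
  denom_in <- sum(abs(xo[inset])^alpha)
  es <- 0
  for (i in seq_len(N)) {
    p_in <- sum(abs(xo[seq_len(i)][inset[seq_len(i)]])^alpha) / denom_in
    p_out <- sum(!inset[seq_len(i)]) / (N - ng)
    es <- es + p_in - p_out
  }
  es
}

# modularity from the defining edge sums (independent of modularity_q)
oracle_modularity <- function(adj, labels, gamma = 1) {
  deg <- rowSums(adj)
  m <- sum(deg) / 2
  if (m == 0) return(0)
  q <- 0
  for (cl in unique(labels)) {
    i <- labels == cl
    e_c <- sum(adj[i, i]) / 2
    d_c <- sum(deg[i])
    q <- q + e_c / m - gamma * (d_c / (2 * m))^2
  }
  q
}

# all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, mx) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (l in seq_len(mx + 1)) rec(c(labels, l), max(mx, l))
  }
  rec(integer(0), 0L)
  out
}

brute_force_max_q <- function(adj, gamma = 1) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(p) oracle_modularity(adj, p, gamma), numeric(1)))
}

# Erdos-Renyi adjacency with ids
random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  ids <- sprintf("n%03d", seq_len(n))
  dimnames(a) <- list(ids, ids)
  a
}

# wrap a plain adjacency as the graph structure the package consumes
as_graph <- function(adj, species = NULL) {
  ids <- rownames(adj)
  structure(list(adj = adj > 0, ids = ids, k = NA,
                 species = if (is.null(species))
                   rep(NA_character_, nrow(adj)) else species,
                 isolated = ids[rowSums(adj) == 0]),
            class = "knn_graph")
}

# adjacency of d disjoint cliques of size s
disjoint_cliques <- function(d = 2, s = 3) {
  n <- d * s
  a <- matrix(0, n, n)
  for (b in seq_len(d)) {
    i <- ((b - 1) * s + 1):(b * s)
    a[i, i] <- 1
  }
  diag(a) <- 0
  dimnames(a) <- list(letters[seq_len(n)], letters[seq_len(n)])
  a
}

# tiny count matrix fixture
tiny_counts <- function(values, genes = NULL, samples = NULL,
                        species = "human") {
  m <- matrix(values, length(genes), length(samples),
              dimnames = list(genes, samples))
  count_matrix(m, species = species)
}

# small simulated cohort for fast module tests
small_cohort <- function(seed = 1, log2_effect = 1.5, ...) {
  simulate_cohort(n_genes = 300, n_orthologs = 250, n_human = 48,
                  n_mouse = 24, k_true = 4, frac_marker = 0.15,
                  log2_effect = log2_effect, seed = seed, ...)
}

# map fitted cluster labels to true labels by majority vote, then score
# agreement of a second label vector under that map
cluster_to_truth_map <- function(cluster, truth) {
  vapply(split(truth, cluster), function(tt)
    as.integer(names(sort(table(tt), decreasing = TRUE))[1]), integer(1))
}
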