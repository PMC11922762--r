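#' Exact k-nearest-neighbour sample graph
#'
#' Builds the undirected, unweighted joint sample graph used for community
#' detection: an edge (i, j) exists iff j is among i's k nearest
#' neighbours or i is among j's (union symmetrization). Neighbour search
#' is exact Euclidean (or Manhattan) on the score coordinates; distance
#' ties are broken by lexicographic sample id. Duplicate coordinates are
#' allowed. Nodes left with degree 0 are flagged as isolated.
#'
#' @param scores samples x rank score matrix with row names
#'   (see [project_scores()], [bind_scores()]).
#' @param k neighbours per node; must satisfy `k < nrow(scores)`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return list with `adj` (logical adjacency matrix), `ids`, `k`,
#'   `species`, `isolated`; class `knn_graph`.
#' @export
knn_graph <- function(scores, k = 20, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  m <- unclass(scores)
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k >= n) stop("k (", k, ") must be smaller than the number of samples (",
                   n, ")")
  d <- as.matrix(stats::dist(m, method = metric))
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di, ids)[seq_len(k)]   # ties by lexicographic sample id
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)                  # union symmetrization
  diag(adj) <- FALSE
  iso <- ids[rowSums(adj) == 0]
  sp <- attr(scores, "species")
  if (is.null(sp)) sp <- rep(NA_character_, n)
  structure(list(adj = adj, ids = ids, k = k, species = sp, isolated = iso),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d nodes, %d edges (k = %d)%s\n",
              length(x$ids), sum(x$adj) / 2, x$k,
              if (length(x$isolated))
                paste0(", ", length(x$isolated), " isolated") else ""))
  invisible(x)
}

#' Newman-Girvan modularity of a labelled graph
#'
#' Q = sum_c [ e_c/m - gamma (d_c/2m)^2 ], where e_c is the number of
#' edges inside community c, d_c the total degree of its nodes and m the
#' number of edges. Used both to score partitions and as an independent
#' check of [louvain()]'s reported optimum.
#'
#' @param graph a [knn_graph()] (or any list with a logical/numeric
#'   symmetric `adj`).
#' @param labels community labels, one per node (in `graph$ids` order or
#'   named by id).
#' @param resolution resolution gamma (1 = standard modularity).
#' @return scalar Q.
#' @export
modularity_q <- function(graph, labels, resolution = 1) {
  adj <- graph$adj * 1
  if (!is.null(names(labels))) labels <- labels[graph$ids]
  if (length(labels) != nrow(adj)) stop("labels must cover all nodes")
  if (anyNA(labels)) stop("labels must cover all nodes")
  deg <- rowSums(adj)
  m2 <- sum(deg)                       # 2m
  if (m2 == 0) return(0)
  q <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    q <- q + sum(adj[idx, idx]) / m2 -
      resolution * (sum(deg[idx]) / m2)^2
  }
  q
}

# one Louvain run: weighted adjacency A (self-loops stored as 2w on the
# diagonal so degrees/weights need no special cases), returns membership
# of the rows of A plus the Q trace across move passes
louvain_once <- function(A, gamma, rng_order) {
  n <- nrow(A)
  level_membership <- list()
  q_trace <- numeric(0)
  repeat {
    k <- rowSums(A)
    m2 <- sum(k)
    comm <- seq_len(nrow(A))
    tot <- k                            # per-community total degree
    improved_level <- FALSE
    repeat {
      moved <- FALSE
      for (i in rng_order(nrow(A))) {
        ci <- comm[i]
        nb <- which(A[i, ] > 0 & seq_len(nrow(A)) != i)
        if (!length(nb)) next
        # link weight from i to each candidate community
        wl <- tapply(A[i, nb], comm[nb], sum)
        cand <- as.integer(names(wl))
        tot[ci] <- tot[ci] - k[i]       # detach i
        w_ci <- if (as.character(ci) %in% names(wl)) wl[[as.character(ci)]] else 0
        # delta-Q (x m2/2) of joining community c, relative to rejoining ci
        score <- 2 * wl / m2 - 2 * gamma * k[i] * tot[cand] / m2^2
        base <- 2 * w_ci / m2 - 2 * gamma * k[i] * tot[ci] / m2^2
        gain <- score - base
        pos <- which(gain > 1e-12)
        if (length(pos)) {
          # ties among maximal gains are broken by the seeded RNG (as in
          # reference implementations, where shuffled neighbour order
          # decides); restarts thereby explore distinct greedy basins,
          # and Q never decreases either way
          mx <- max(gain[pos])
          tie <- pos[abs(gain[pos] - mx) < 1e-14]
          pick <- if (length(tie) == 1) tie else tie[sample.int(length(tie), 1)]
          newc <- cand[pick]
          comm[i] <- newc
          tot[newc] <- tot[newc] + k[i]
          moved <- TRUE
          improved_level <- TRUE
        } else {
          tot[ci] <- tot[ci] + k[i]     # put i back
        }
      }
      q_trace <- c(q_trace, weighted_q(A, comm, gamma))
      if (!moved) break
    }
    comm <- match(comm, sort(unique(comm)))
    level_membership[[length(level_membership) + 1]] <- comm
    if (!improved_level || length(unique(comm)) == nrow(A)) break
    # aggregate communities into super-nodes
    nc <- max(comm)
    P <- matrix(0, nrow(A), nc)
    P[cbind(seq_len(nrow(A)), comm)] <- 1
    A <- t(P) %*% A %*% P
  }
  memb <- level_membership[[1]]
  for (lv in level_membership[-1]) memb <- lv[memb]
  list(membership = memb, q_trace = q_trace)
}

weighted_q <- function(A, comm, gamma) {
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (c in unique(comm)) {
    idx <- which(comm == c)
    q <- q + sum(A[idx, idx]) / m2 - gamma * (sum(k[idx]) / m2)^2
  }
  q
}

#' Louvain community detection
#'
#' Greedy modularity optimization: repeated seeded-order local node moves
#' (each accepted move strictly increases Q), then aggregation of
#' communities into super-nodes, until no move improves Q. With
#' `n_restarts > 1` the algorithm is re-run with seeds
#' `seed, seed + 1, ...` and the best-Q partition is kept.
#'
#' Cluster labels are renumbered deterministically: 1 is the cluster with
#' the most human samples (per the graph's species tags), ties broken by
#' total size, then by lexicographic smallest member id. Isolated nodes
#' form singleton clusters.
#'
#' @param graph a [knn_graph()].
#' @param resolution resolution gamma (default 1).
#' @param seed integer seed controlling the node visiting order.
#' @param n_restarts number of seeded restarts; best Q wins.
#' @return list with `labels` (named integer vector, contiguous from 1),
#'   `Q`, `resolution`, `seed`, `q_trace`, `species`; class
#'   `cluster_assignment`.
#' @export
louvain <- function(graph, resolution = 1, seed = 0, n_restarts = 1) {
  stopifnot(inherits(graph, "knn_graph") || !is.null(graph$adj))
  n <- length(graph$ids)
  if (n == 0) stop("empty graph")
  A <- graph$adj * 1
  if (sum(A) == 0) {
    labels <- stats::setNames(seq_len(n), graph$ids)
    return(structure(list(labels = labels, Q = 0, resolution = resolution,
                          seed = seed, q_trace = 0,
                          species = stats::setNames(graph$species, graph$ids),
                          isolated = graph$isolated),
                     class = "cluster_assignment"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    s <- seed + r - 1
    rng_order <- local({
      s0 <- s
      first <- TRUE
      function(nn) {
        if (first) { set.seed(s0); first <<- FALSE }
        sample.int(nn)
      }
    })
    run <- louvain_once(A, resolution, rng_order)
    if (is.null(best) || max(run$q_trace) > best$qmax + 1e-12) {
      best <- list(run = run, qmax = max(run$q_trace), seed = s)
    }
  }
  memb <- best$run$membership
  labels <- relabel_clusters(memb, graph$ids, graph$species)
  Q <- modularity_q(graph, labels, resolution)
  structure(list(labels = labels, Q = Q, resolution = resolution,
                 seed = best$seed, q_trace = best$run$q_trace,
                 species = stats::setNames(graph$species, graph$ids),
                 isolated = graph$isolated),
            class = "cluster_assignment")
}

# deterministic label ordering: decreasing human count, then total size,
# then lexicographic smallest member
relabel_clusters <- function(memb, ids, species) {
  u <- sort(unique(memb))
  hum <- vapply(u, function(c) sum(species[memb == c] == "human", na.rm = TRUE),
                numeric(1))
  tot <- vapply(u, function(c) sum(memb == c), numeric(1))
  first <- vapply(u, function(c) min(ids[memb == c]), character(1))
  ord <- u[order(-hum, -tot, first)]
  stats::setNames(match(memb, ord), ids)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("cluster_assignment: %d clusters over %d samples (Q = %.4f, gamma = %g)\n",
              length(tab), length(x$labels), x$Q, x$resolution))
  print(tab)
  invisible(x)
}

#' Assign cluster labels to new samples
#'
#' Two attribution modes for samples projected into an existing latent
#' space. `"nearest_reference"` (default, stable): each new sample takes
#' the majority label among its `k_vote` nearest reference samples, ties
#' resolved to the smallest cluster label. `"joint"`: the kNN graph and
#' Louvain are re-run on the union of reference and new samples, and each
#' joint community is mapped to the reference label with which it overlaps
#' most (a joint community containing no reference sample falls back to
#' nearest-reference voting for its members).
#'
#' @param s_new,s_ref samples x rank score matrices from the same
#'   [fit_human_space()] space (verified via the space hash when present).
#' @param ref_labels a `cluster_assignment` for the reference samples (or
#'   a named label vector).
#' @param mode `"nearest_reference"` or `"joint"`.
#' @param k_vote neighbours for majority voting.
#' @param k,resolution,seed joint-mode graph/Louvain parameters.
#' @return a `cluster_assignment` for the new samples (labels in the
#'   reference label space; `Q` is `NA` in nearest-reference mode).
#' @export
classify_new <- function(s_new, s_ref, ref_labels,
                         mode = c("nearest_reference", "joint"),
                         k_vote = 15, k = 20, resolution = 1, seed = 0) {
  mode <- match.arg(mode)
  h1 <- attr(s_new, "space_genes_hash")
  h2 <- attr(s_ref, "space_genes_hash")
  if (!is.null(h1) && !is.null(h2) && !is.na(h1) && !is.na(h2) && h1 != h2)
    stop("score matrices come from different embedding spaces")
  lab_ref <- if (inherits(ref_labels, "cluster_assignment"))
    ref_labels$labels else ref_labels
  lab_ref <- lab_ref[rownames(s_ref)]
  if (anyNA(lab_ref)) stop("reference labels must cover all reference samples")
  if (mode == "nearest_reference") {
    labels <- vote_nearest(s_new, s_ref, lab_ref, k_vote)
  } else {
    joint <- bind_scores(s_ref, s_new)
    g <- knn_graph(joint, k = k)
    cl <- louvain(g, resolution = resolution, seed = seed)
    jl <- cl$labels
    labels <- stats::setNames(integer(nrow(s_new)), rownames(s_new))
    for (c in unique(jl)) {
      members <- names(jl)[jl == c]
      refm <- intersect(members, rownames(s_ref))
      newm <- intersect(members, rownames(s_new))
      if (!length(newm)) next
      if (length(refm)) {
        ov <- table(lab_ref[refm])
        lab <- min(as.integer(names(ov)[ov == max(ov)]))
        labels[newm] <- lab
      } else {
        labels[newm] <- vote_nearest(s_new[newm, , drop = FALSE], s_ref,
                                     lab_ref, k_vote)
      }
    }
  }
  sp <- attr(s_new, "species")
  if (is.null(sp)) sp <- rep(NA_character_, nrow(s_new))
  structure(list(labels = labels, Q = NA_real_, resolution = resolution,
                 seed = seed, q_trace = numeric(0),
                 species = stats::setNames(sp, rownames(s_new)),
                 mode = mode),
            class = "cluster_assignment")
}

vote_nearest <- function(s_new, s_ref, lab_ref, k_vote) {
  k_vote <- min(k_vote, nrow(s_ref))
  ref_ids <- rownames(s_ref)
  out <- integer(nrow(s_new))
  for (i in seq_len(nrow(s_new))) {
    d <- sqrt(colSums((t(unclass(s_ref)) - as.numeric(s_new[i, ]))^2))
    nb <- order(d, ref_ids)[seq_len(k_vote)]
    tab <- table(lab_ref[nb])
    out[i] <- min(as.integer(names(tab)[tab == max(tab)]))
  }
  stats::setNames(out, rownames(s_new))
}
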