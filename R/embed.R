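#' Fit the rank-r human latent space by SVD
#'
#' Computes the singular value decomposition of the centred human
#' genes x samples matrix and retains the top `rank` left singular vectors
#' (gene loadings). Each loading column's sign is fixed so that its
#' largest-magnitude entry is positive, making the factorization
#' deterministic across runs and platforms. Mouse (or any other) cohorts
#' are later projected into this frozen frame with [project_scores()].
#'
#' @param e_human centred genes x samples expression matrix
#'   (see [center_within_sample()]).
#' @param rank number of components to keep (the analysis default is 100).
#' @return list with `gene_loadings` (genes x rank, orthonormal columns),
#'   `singular_values` (non-increasing), `rank`, `gene_order`; class
#'   `embedding_space`.
#' @export
fit_human_space <- function(e_human, rank = 100) {
  m <- unclass(e_human)
  maxr <- min(dim(m))
  if (rank > maxr) {
    warning("rank ", rank, " exceeds min(genes, samples) = ", maxr,
            "; reduced to ", maxr)
    rank <- maxr
  }
  sv <- svd(m, nu = rank, nv = 0)
  u <- sv$u
  # sign convention: largest-magnitude entry of each column positive
  flip <- vapply(seq_len(ncol(u)), function(j) {
    i <- which.max(abs(u[, j]))
    sign(u[i, j])
  }, numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(u, 2, flip, "*")
  rownames(u) <- rownames(m)
  structure(list(gene_loadings = u,
                 singular_values = sv$d[seq_len(rank)],
                 rank = rank,
                 gene_order = rownames(m)),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("embedding_space: rank %d over %d genes (top singular value %.3g)\n",
              x$rank, length(x$gene_order), x$singular_values[1]))
  invisible(x)
}

#' Project samples into a fitted latent space
#'
#' Coordinates are `t(e) %*% gene_loadings` (samples x rank), i.e. the
#' unwhitened, singular-value-scaled scores: projecting the human training
#' matrix itself reproduces its own SVD sample scores. The loadings are
#' used unchanged for every cohort (frozen human reference frame).
#'
#' Genes are matched by id to the space's training genes. Incomplete
#' overlap warns; overlap below 80% is an error. Missing genes contribute
#' zero.
#'
#' @param e centred genes x samples expression matrix.
#' @param space an `embedding_space` from [fit_human_space()].
#' @param species species tag attached to the result rows (optional).
#' @return samples x rank score matrix with attributes `species` and
#'   `space_genes_hash`.
#' @export
project_scores <- function(e, space, species = NULL) {
  stopifnot(inherits(space, "embedding_space"))
  m <- unclass(e)
  ov <- intersect(space$gene_order, rownames(m))
  frac <- length(ov) / length(space$gene_order)
  if (frac < 0.8)
    stop(sprintf("only %.1f%% of the space's genes are present; >= 80%% required",
                 100 * frac))
  if (frac < 1)
    warning(sprintf("%.1f%% gene overlap with the embedding space; missing genes treated as 0",
                    100 * frac))
  full <- matrix(0, length(space$gene_order), ncol(m),
                 dimnames = list(space$gene_order, colnames(m)))
  full[ov, ] <- m[ov, , drop = FALSE]
  s <- crossprod(full, space$gene_loadings)   # samples x rank
  rownames(s) <- colnames(m)
  colnames(s) <- paste0("PC", seq_len(ncol(s)))
  attr(s, "species") <- if (is.null(species)) rep(NA_character_, nrow(s)) else
    rep_len(species, nrow(s))
  attr(s, "space_genes_hash") <- space_hash(space)
  s
}

space_hash <- function(space) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(space$gene_order, f)
  unname(tools::md5sum(f))
}

#' Stack score matrices from several cohorts
#'
#' @param ... samples x rank score matrices from the same
#'   [fit_human_space()] space.
#' @return one score matrix with species attributes concatenated.
#' @export
bind_scores <- function(...) {
  parts <- list(...)
  hashes <- unique(vapply(parts, function(p) {
    h <- attr(p, "space_genes_hash")
    if (is.null(h)) NA_character_ else h
  }, character(1)))
  hashes <- hashes[!is.na(hashes)]
  if (length(hashes) > 1)
    stop("score matrices come from different embedding spaces")
  s <- do.call(rbind, lapply(parts, unclass))
  attr(s, "species") <- unlist(lapply(parts, function(p) {
    sp <- attr(p, "species")
    if (is.null(sp)) rep(NA_character_, nrow(p)) else sp
  }))
  attr(s, "space_genes_hash") <- if (length(hashes)) hashes else NA_character_
  s
}

#' 2-D UMAP layout of sample scores
#'
#' Visualization-only embedding of the samples x rank score matrix;
#' clustering never consumes these coordinates. Seed-reproducible
#' (single-threaded exact nearest neighbours). If fewer than
#' `n_neighbors + 1` samples are supplied, `n_neighbors` is shrunk with a
#' warning.
#'
#' @param scores samples x rank matrix.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed integer RNG seed.
#' @return samples x 2 coordinate matrix.
#' @export
umap_embed <- function(scores, n_neighbors = 15, min_dist = 0.1, seed = 0) {
  n <- nrow(scores)
  if (n < n_neighbors + 1) {
    n_neighbors <- max(2, n - 1)
    warning("fewer samples than n_neighbors + 1; n_neighbors shrunk to ",
            n_neighbors)
  }
  set.seed(seed)
  xy <- uwot::umap(unclass(scores), n_neighbors = n_neighbors,
                   min_dist = min_dist, n_threads = 1, n_sgd_threads = 1,
                   nn_method = "fnn", verbose = FALSE)
  rownames(xy) <- rownames(scores)
  colnames(xy) <- c("UMAP1", "UMAP2")
  xy
}
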