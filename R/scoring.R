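#' Single-sample GSEA enrichment score for one sample
#'
#' Barbie-type weighted running-sum statistic. Genes are ranked by
#' expression, descending, ties broken by gene id; walking down the ranked
#' list, the in-set cumulative weight (weights `|x|^alpha`, normalized
#' over the set) is compared at every position with the out-of-set
#' cumulative count (normalized over the `N - |G|` non-members), and the
#' score is the sum of the differences over all N positions:
#' `ES = sum_i [P_in(i) - P_out(i)]`. `|ES| <= N` always.
#'
#' @param x named numeric expression vector for one sample.
#' @param gene_set character vector of gene ids.
#' @param alpha rank weighting exponent (0 = rank-only; 0.25 is the
#'   classical ssGSEA weight).
#' @return scalar ES, or `NA` with a warning if the set does not
#'   intersect the gene space.
#' @export
ssgsea_sample <- function(x, gene_set, alpha = 0.25) {
  genes <- names(x)
  if (is.null(genes)) stop("expression vector must be named by gene id")
  inset <- genes %in% gene_set
  ng <- sum(inset)
  if (ng == 0) {
    warning("gene set does not intersect the expression gene space")
    return(NA_real_)
  }
  if (ng >= length(x))
    stop("gene set must be a strict subset of the gene space")
  ord <- order(-x, genes)
  w <- abs(x)^alpha * inset
  denom_in <- sum(w)
  p_in <- if (denom_in > 0) cumsum(w[ord]) / denom_in else
    cumsum(inset[ord]) / ng       # all-zero in-set weights: flat ECDF
  p_out <- cumsum(!inset[ord]) / (length(x) - ng)
  sum(p_in - p_out)
}

#' ssGSEA score matrix
#'
#' Applies [ssgsea_sample()] to every (gene set, sample) pair. With
#' `normalize = TRUE`, each set's row of scores is min-max scaled to
#' [0, 1] across samples (order-preserving).
#'
#' @param e genes x samples expression matrix (typically the per-species
#'   VST matrix, not centred, with mouse ids translated to human so
#'   human-symbol sets apply to both species).
#' @param sets a [gene_set_collection()] (or named list).
#' @param alpha rank weighting exponent.
#' @param normalize min-max scale each row.
#' @return sets x samples numeric matrix with attributes `alpha` and
#'   `normalization` (`"raw"` or `"minmax"`).
#' @export
ssgsea_matrix <- function(e, sets, alpha = 0.25, normalize = FALSE) {
  m <- unclass(e)
  out <- matrix(NA_real_, length(sets), ncol(m),
                dimnames = list(names(sets), colnames(m)))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    names(x) <- rownames(m)
    for (i in seq_along(sets))
      out[i, j] <- ssgsea_sample(x, sets[[i]], alpha = alpha)
  }
  if (normalize) {
    rng <- apply(out, 1, function(r) diff(range(r, na.rm = TRUE)))
    out <- (out - apply(out, 1, min, na.rm = TRUE)) / ifelse(rng > 0, rng, 1)
  }
  attr(out, "alpha") <- alpha
  attr(out, "normalization") <- if (normalize) "minmax" else "raw"
  out
}

#' Maximal-enrichment subclass assignment
#'
#' Each sample is assigned the subclass whose enrichment score is highest
#' (the Hoshida/Chiang-style "highest enriched subclass" rule). Exact
#' ties go to the lexicographically smallest subclass name and are
#' flagged.
#'
#' @param enr sets x samples enrichment matrix (see [ssgsea_matrix()]).
#' @param subclass_sets names of the rows to compare.
#' @return data.frame with `sample_id`, `subclass`, `tie`.
#' @export
assign_subclass_max <- function(enr, subclass_sets = rownames(enr)) {
  missing_sets <- setdiff(subclass_sets, rownames(enr))
  if (length(missing_sets))
    stop("subclass set(s) not in enrichment matrix: ",
         paste(missing_sets, collapse = ", "))
  sub <- enr[subclass_sets, , drop = FALSE]
  res <- lapply(seq_len(ncol(sub)), function(j) {
    v <- sub[, j]
    mx <- max(v)
    hits <- sort(rownames(sub)[v == mx])
    data.frame(sample_id = colnames(sub)[j], subclass = hits[1],
               tie = length(hits) > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Nearest Template Prediction with permutation significance
#'
#' Classifies each sample by cosine distance to class marker templates.
#' Expression is restricted to the union of all marker genes; each
#' class's template is +1 on its own markers and 0 elsewhere (signed
#' templates with -1 "down" markers are supported via `weights`). The
#' predicted class minimizes d = 1 - cosine similarity (d in [0, 2]; a
#' zero-norm vector is assigned d = 1).
#'
#' Significance: for each of `n_perm` permutations one random marker set
#' per class (matching that class's size, drawn uniformly from all genes
#' of `e`) is generated and the minimum distance over classes is taken,
#' replicating the selection step, so null p-values are uniform;
#' `p = (1 + #(d_null <= d_pred)) / (1 + n_perm)` (always > 0). FDR is
#' Benjamini-Hochberg across the cohort's samples.
#'
#' @param e genes x samples expression matrix.
#' @param templates named list: class name -> character vector of marker
#'   gene ids (>= 2 classes).
#' @param weights optional named list mirroring `templates` with +1/-1
#'   per marker (default all +1).
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return data.frame with `sample_id`, `class`, `distance`, `p_value`,
#'   `fdr`.
#' @export
ntp_classify <- function(e, templates, weights = NULL, n_perm = 1000,
                         seed = 0) {
  m <- unclass(e)
  genes <- rownames(m)
  templates <- lapply(templates, function(g) unique(as.character(g)))
  keep <- vapply(templates, function(g) any(g %in% genes), logical(1))
  if (any(!keep))
    warning("class(es) with no markers in the gene space dropped: ",
            paste(names(templates)[!keep], collapse = ", "))
  templates <- templates[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(templates) < 2)
    stop("fewer than 2 classes with markers present in the gene space")
  templates <- lapply(templates, function(g) intersect(g, genes))
  if (is.null(weights)) weights <- lapply(templates, function(g) rep(1, length(g)))
  weights <- lapply(seq_along(templates), function(i)
    rep_len(weights[[i]], length(templates[[i]])))
  names(weights) <- names(templates)
  d_obs <- template_distances(m, templates, weights)
  pred_idx <- apply(d_obs, 2, which.min)
  d_pred <- d_obs[cbind(pred_idx, seq_len(ncol(d_obs)))]
  # null: per permutation draw one random marker set per class (same
  # sizes and weights, drawn from all genes) and take the min distance,
  # replicating the argmin selection of the observed statistic
  set.seed(seed)
  sizes <- lengths(templates)
  exceed <- numeric(ncol(m))
  for (b in seq_len(n_perm)) {
    rand <- lapply(sizes, function(s) sample(genes, s))
    d_null <- template_distances(m, rand, weights)
    exceed <- exceed + (apply(d_null, 2, min) <= d_pred + 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(sample_id = colnames(m),
             class = names(templates)[pred_idx],
             distance = d_pred,
             p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

cosine_dist <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(1)
  1 - sum(x * y) / (nx * ny)
}

# classes x samples cosine distances between each sample's expression,
# restricted to the union of the given marker sets, and each class's
# signed template (weights on its markers, 0 elsewhere)
template_distances <- function(m, marker_sets, weights) {
  union_genes <- unique(unlist(marker_sets))
  sub <- m[union_genes, , drop = FALSE]
  tmat <- vapply(seq_along(marker_sets), function(c) {
    v <- numeric(length(union_genes))
    v[match(marker_sets[[c]], union_genes)] <- weights[[c]]
    v
  }, numeric(length(union_genes)))
  num <- crossprod(tmat, sub)                     # classes x samples
  nx <- sqrt(colSums(sub^2))                      # per-sample union norm
  nt <- sqrt(colSums(tmat^2))                     # per-class template norm
  cosm <- num / outer(nt, nx)
  cosm[, nx == 0] <- 0
  cosm[nt == 0, ] <- 0
  d <- 1 - cosm
  rownames(d) <- names(marker_sets)
  d
}
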