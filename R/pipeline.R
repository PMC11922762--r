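#' Fit the cross-species disease-positioning model
#'
#' The package's central fitting function. Starting from raw human and
#' mouse count matrices and a one-to-one ortholog map it runs, in order:
#' per-species variance-stabilizing normalization ([normalize_counts()]),
#' ortholog harmonization onto the human gene namespace ([harmonize()]),
#' within-sample centring ([center_within_sample()]), SVD of the human
#' matrix into a rank-r latent space ([fit_human_space()]), projection of
#' both species into that frozen space ([project_scores()]), an exact
#' k-nearest-neighbour joint sample graph ([knn_graph()]), Louvain
#' community detection ([louvain()]) yielding the shared "HuMo" clusters,
#' and (optionally) a 2-D UMAP layout for visualization only.
#'
#' @param human,mouse [count_matrix()] objects (genes x samples, raw
#'   counts).
#' @param omap an [ortholog_map()].
#' @param rank latent-space rank (default 100, reduced with a warning if
#'   it exceeds the matrix rank).
#' @param knn_k neighbours for the sample graph.
#' @param resolution Louvain resolution gamma.
#' @param seed seed for Louvain's node ordering and the UMAP layout.
#' @param n_restarts Louvain restarts (best Q kept).
#' @param umap compute the 2-D layout (visualization only).
#' @param n_neighbors,min_dist UMAP parameters.
#' @return an object of class `humo_fit`: `space` (embedding_space),
#'   `scores` (joint samples x rank), `clusters` (cluster_assignment),
#'   `graph`, `umap` (or NULL), `vst` (per-species normalization:
#'   size_factors, trend), `expr` (harmonized un-centred VST matrices,
#'   human gene ids, for gene-set scoring), `ortholog_map`, `params`.
#' @seealso [predict.humo_fit()], [run_pipeline()]
#' @examples
#' \donttest{
#' sim <- simulate_cohort(n_genes = 400, n_orthologs = 300, n_human = 60,
#'                        n_mouse = 30, seed = 1)
#' fit <- humo_fit(sim$human_counts, sim$mouse_counts, sim$ortholog_map,
#'                 rank = 20, knn_k = 10, umap = FALSE)
#' summary(fit)
#' }
#' @export
humo_fit <- function(human, mouse, omap, rank = 100, knn_k = 20,
                     resolution = 1, seed = 0, n_restarts = 1,
                     umap = TRUE, n_neighbors = 15, min_dist = 0.1) {
  stopifnot(attr(human, "species") %in% c("human", NA),
            attr(mouse, "species") %in% c("mouse", NA))
  nh <- normalize_counts(human)
  nm <- normalize_counts(mouse)
  harm <- harmonize(nh$vst, nm$vst, omap)
  ch <- center_within_sample(harm$human)
  cm <- center_within_sample(harm$mouse)
  space <- fit_human_space(ch, rank = rank)
  sh <- project_scores(ch, space, species = "human")
  sm <- project_scores(cm, space, species = "mouse")
  scores <- bind_scores(sh, sm)
  graph <- knn_graph(scores, k = knn_k)
  clusters <- louvain(graph, resolution = resolution, seed = seed,
                      n_restarts = n_restarts)
  layout <- if (umap)
    umap_embed(scores, n_neighbors = n_neighbors, min_dist = min_dist,
               seed = seed) else NULL
  structure(list(space = space, scores = scores, clusters = clusters,
                 graph = graph, umap = layout,
                 vst = list(human = list(size_factors = nh$size_factors,
                                         trend = nh$trend),
                            mouse = list(size_factors = nm$size_factors,
                                         trend = nm$trend)),
                 expr = harm, ortholog_map = omap,
                 params = list(rank = space$rank, knn_k = knn_k,
                               resolution = resolution, seed = seed)),
            class = "humo_fit")
}

#' @export
print.humo_fit <- function(x, ...) {
  cat("Cross-species disease-positioning fit\n")
  cat(sprintf("  latent space: rank %d over %d shared ortholog genes\n",
              x$space$rank, length(x$space$gene_order)))
  cat(sprintf("  samples: %d human + %d mouse\n",
              sum(x$clusters$species == "human"),
              sum(x$clusters$species == "mouse")))
  cat(sprintf("  clusters: %d (Louvain Q = %.4f, gamma = %g, k = %d)\n",
              length(unique(x$clusters$labels)), x$clusters$Q,
              x$params$resolution, x$params$knn_k))
  invisible(x)
}

#' @export
summary.humo_fit <- function(object, ...) {
  tab <- table(cluster = object$clusters$labels,
               species = object$clusters$species)
  out <- list(cluster_by_species = tab, Q = object$clusters$Q,
              n_clusters = length(unique(object$clusters$labels)),
              params = object$params,
              isolated = object$clusters$isolated)
  class(out) <- "summary.humo_fit"
  out
}

#' @export
print.summary.humo_fit <- function(x, ...) {
  cat(sprintf("HuMo clustering: %d clusters, modularity Q = %.4f\n",
              x$n_clusters, x$Q))
  print(x$cluster_by_species)
  if (length(x$isolated))
    cat("isolated samples (singleton clusters):",
        paste(x$isolated, collapse = ", "), "\n")
  cat(sprintf("parameters: rank = %d, k = %d, gamma = %g, seed = %d\n",
              x$params$rank, x$params$knn_k, x$params$resolution,
              x$params$seed))
  invisible(x)
}

#' Cluster labels of a fitted model
#' @param fit a `humo_fit`.
#' @return named integer vector of cluster labels.
#' @export
cluster_labels <- function(fit) fit$clusters$labels

#' Classify a new cohort against a fitted model
#'
#' Normalizes the new cohort with its own size factors and dispersion
#' trend, translates mouse gene ids through the stored ortholog map,
#' centres within sample on the latent space's gene axis, projects into
#' the frozen human space (gene overlap below 80% is an error), and
#' assigns each sample a cluster label via [classify_new()].
#'
#' @param object a `humo_fit`.
#' @param newdata a [count_matrix()] for the new cohort.
#' @param mode `"nearest_reference"` (default) or `"joint"`.
#' @param k_vote neighbours for nearest-reference voting.
#' @param ... unused.
#' @return a `cluster_assignment` for the new samples (see
#'   [validate_external_cohort()] for the annotated data-frame variant).
#' @export
predict.humo_fit <- function(object, newdata,
                             mode = c("nearest_reference", "joint"),
                             k_vote = 15, ...) {
  mode <- match.arg(mode)
  sp <- attr(newdata, "species")
  if (is.null(sp)) sp <- "human"
  nn <- normalize_counts(newdata)
  v <- nn$vst
  if (sp == "mouse") {
    hit <- rownames(v) %in% object$ortholog_map$mouse
    v <- v[hit, , drop = FALSE]
    rownames(v) <- object$ortholog_map$human[
      match(rownames(v), object$ortholog_map$mouse)]
  }
  shared <- intersect(object$space$gene_order, rownames(v))
  if (length(shared) / length(object$space$gene_order) < 0.8)
    stop(sprintf("only %.1f%% of the model's genes found in the new cohort; >= 80%% required",
                 100 * length(shared) / length(object$space$gene_order)))
  cen <- center_within_sample(v[shared, , drop = FALSE])
  s_new <- project_scores(cen, object$space, species = sp)
  classify_new(s_new, object$scores, object$clusters, mode = mode,
               k_vote = k_vote, k = object$params$knn_k,
               resolution = object$params$resolution,
               seed = object$params$seed)
}

#' Plot the UMAP layout of a fitted model
#'
#' Base-graphics scatter of the 2-D layout, coloured by cluster, with
#' mouse samples drawn as triangles. Purely decorative: clustering never
#' uses these coordinates.
#'
#' @param x a `humo_fit` fitted with `umap = TRUE`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.humo_fit <- function(x, ...) {
  if (is.null(x$umap))
    stop("model was fitted with umap = FALSE; no layout to plot")
  lab <- x$clusters$labels[rownames(x$umap)]
  sp <- x$clusters$species[rownames(x$umap)]
  graphics::plot(x$umap, col = lab, pch = ifelse(sp == "mouse", 17, 16),
                 xlab = "UMAP1", ylab = "UMAP2", ...)
  graphics::legend("topright",
                   legend = c(paste("HuMo", sort(unique(lab))),
                              "human", "mouse"),
                   col = c(sort(unique(lab)), "black", "black"),
                   pch = c(rep(15, length(unique(lab))), 16, 17),
                   bty = "n")
  invisible(x)
}

#' Run the full disease-positioning pipeline from a config
#'
#' File-driven orchestration of [humo_fit()] plus the downstream
#' characterization stages: gene-set scoring, maximal-enrichment
#' subclassing, the cluster-by-feature Fisher panel and the cluster
#' survival comparison. All intermediates are written to
#' `config$out_dir`, and a machine-readable run report (parameters,
#' cluster sizes by species, modularity, md5 hashes of every input and
#' output file) is written as `run_report.json`. Any stage failure
#' aborts with a stage-named error. Reruns with identical inputs, config
#' and seeds are bit-identical.
#'
#' @param config a named list or path to a JSON file with fields:
#'   `human_counts`, `mouse_counts`, `ortholog_map` (paths; required),
#'   `format` ("tsv"/"mtx"), `gene_sets` (GMT path, optional),
#'   `subclass_sets` (names within the GMT, optional), `metadata` (TSV
#'   path, optional), `features` (metadata columns for the Fisher panel,
#'   optional), `rank` (default 100), `knn_k` (20), `resolution` (1),
#'   `alpha` (0.25), `seed` (0), `umap` (TRUE), `out_dir` (required).
#' @return the run report, invisibly (list; also on disk). The fitted
#'   model is saved alongside as `labels.tsv`, `scores.tsv`,
#'   `loadings.tsv`, `space.json`, plus stage outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(format = "tsv", rank = 100, knn_k = 20, resolution = 1,
                   alpha = 0.25, seed = 0, umap = TRUE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (req in c("human_counts", "mouse_counts", "ortholog_map", "out_dir"))
    if (is.null(config[[req]])) stop("config is missing required field: ", req)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  in_paths <- c(human_counts = config$human_counts,
                mouse_counts = config$mouse_counts,
                ortholog_map = config$ortholog_map)
  if (!is.null(config$gene_sets)) in_paths["gene_sets"] <- config$gene_sets
  if (!is.null(config$metadata)) in_paths["metadata"] <- config$metadata

  human <- stage("read_counts(human)",
                 read_counts(config$human_counts, config$format, "human"))
  mouse <- stage("read_counts(mouse)",
                 read_counts(config$mouse_counts, config$format, "mouse"))
  omap <- stage("harmonize", read_ortholog_map(config$ortholog_map))
  fit <- stage("fit", humo_fit(human, mouse, omap, rank = config$rank,
                               knn_k = config$knn_k,
                               resolution = config$resolution,
                               seed = config$seed, umap = config$umap))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  lab_df <- data.frame(sample_id = names(fit$clusters$labels),
                       species = unname(fit$clusters$species),
                       cluster = unname(fit$clusters$labels))
  utils::write.table(lab_df, out("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(fit$scores, out("scores.tsv"), "sample_id")
  write_matrix_tsv(fit$space$gene_loadings, out("loadings.tsv"), "gene_id")
  jsonlite::write_json(list(rank = fit$space$rank,
                            singular_values = fit$space$singular_values,
                            gene_order_hash = space_hash(fit$space)),
                       out("space.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$umap)) write_matrix_tsv(fit$umap, out("umap.tsv"),
                                           "sample_id")

  enr <- NULL
  subclass <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- stage("read_gmt", read_gmt(config$gene_sets))
    expr_joint <- cbind(fit$expr$human, fit$expr$mouse)
    enr <- stage("ssgsea", ssgsea_matrix(expr_joint, sets,
                                         alpha = config$alpha))
    write_matrix_tsv(enr, out("ssgsea.tsv"), "gene_set")
    if (!is.null(config$subclass_sets)) {
      subclass <- stage("subclass",
                        assign_subclass_max(enr, config$subclass_sets))
      utils::write.table(subclass, out("subclass.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  panel <- NULL
  surv <- NULL
  if (!is.null(config$metadata)) {
    meta <- stage("read_metadata", read_metadata(config$metadata))
    if (!is.null(config$features)) {
      panel <- stage("associations",
                     cluster_feature_panel(fit$clusters, meta,
                                           config$features))
      utils::write.table(panel, out("feature_panel.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (all(c("time", "event") %in% names(meta))) {
      surv <- stage("survival", {
        idx <- match(names(fit$clusters$labels), meta$sample_id)
        ok <- !is.na(idx) & !is.na(meta$time[idx]) & !is.na(meta$event[idx])
        km <- km_curves(meta$time[idx][ok], meta$event[idx][ok],
                        fit$clusters$labels[ok])
        lr <- logrank_test(meta$time[idx][ok], meta$event[idx][ok],
                           fit$clusters$labels[ok])
        utils::write.table(km, out("km_curves.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        lr
      })
    }
  }

  out_files <- list.files(config$out_dir, full.names = TRUE)
  out_files <- setdiff(out_files, out("run_report.json"))
  report <- list(
    parameters = config[c("rank", "knn_k", "resolution", "alpha", "seed",
                          "format")],
    n_clusters = length(unique(fit$clusters$labels)),
    modularity = fit$clusters$Q,
    cluster_sizes = as.list(as.data.frame.matrix(
      table(fit$clusters$labels, fit$clusters$species))),
    logrank = surv,
    input_hashes = as.list(tools::md5sum(in_paths)),
    output_hashes = as.list(tools::md5sum(out_files)))
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(report, "fit") <- fit
  invisible(report)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify and annotate an external validation cohort
#'
#' Mirrors the validation workflow for an independent cohort against a
#' frozen reference fit: the new cohort is normalized with its own size
#' factors and dispersion trend, projected into the reference latent
#' space, labelled via [predict.humo_fit()], and optionally annotated by
#' Nearest Template Prediction and maximal-enrichment subclassing.
#'
#' @param fit a `humo_fit`.
#' @param new_counts a [count_matrix()] for the validation cohort.
#' @param mode attribution mode, see [classify_new()].
#' @param templates optional named list of class marker genes for
#'   [ntp_classify()].
#' @param subclass_sets optional [gene_set_collection()] scored by ssGSEA
#'   and assigned by [assign_subclass_max()].
#' @param alpha ssGSEA exponent.
#' @param n_perm,seed NTP permutation parameters.
#' @return data.frame with `sample_id`, `cluster`, and (if requested)
#'   `ntp_class`, `ntp_distance`, `ntp_p`, `ntp_fdr`, `subclass`.
#' @export
validate_external_cohort <- function(fit, new_counts,
                                     mode = c("nearest_reference", "joint"),
                                     templates = NULL, subclass_sets = NULL,
                                     alpha = 0.25, n_perm = 1000, seed = 0) {
  mode <- match.arg(mode)
  cl <- predict(fit, new_counts, mode = mode)
  out <- data.frame(sample_id = names(cl$labels),
                    cluster = unname(cl$labels), stringsAsFactors = FALSE)
  if (!is.null(templates) || !is.null(subclass_sets)) {
    v <- normalize_counts(new_counts)$vst
    if (!is.null(templates)) {
      ntp <- ntp_classify(v, templates, n_perm = n_perm, seed = seed)
      out$ntp_class <- ntp$class[match(out$sample_id, ntp$sample_id)]
      out$ntp_distance <- ntp$distance[match(out$sample_id, ntp$sample_id)]
      out$ntp_p <- ntp$p_value[match(out$sample_id, ntp$sample_id)]
      out$ntp_fdr <- ntp$fdr[match(out$sample_id, ntp$sample_id)]
    }
    if (!is.null(subclass_sets)) {
      enr <- ssgsea_matrix(v, subclass_sets, alpha = alpha)
      sc <- assign_subclass_max(enr)
      out$subclass <- sc$subclass[match(out$sample_id, sc$sample_id)]
    }
  }
  out
}
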