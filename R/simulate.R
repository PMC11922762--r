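#' Simulate a paired human/mouse cohort with planted subtypes
#'
#' Generates gene-level negative-binomial count matrices for a human and
#' a mouse cohort sharing `k_true` transcriptional subtypes, the
#' statistical structure the cross-species positioning pipeline assumes:
#'
#' * Every sample gets one subtype, drawn uniformly (or per `subtype_prob`).
#' * A disjoint block of marker genes per subtype, chosen only among the
#'   orthologs so the shared signal survives harmonization, is shifted by
#'   `log2_effect` log2 units (random sign per gene) in that subtype.
#'   Non-ortholog genes carry noise only.
#' * Orthologous genes share one baseline log2 expression profile; mouse
#'   samples additionally receive a per-gene species offset drawn once
#'   (s.d. `species_shift_sd` log2 units), modelling the cross-species
#'   baseline shift the rank-r projection must absorb.
#' * Per-sample expected library sizes are uniform on `lib_size_range`;
#'   a sample's expected gene counts are `libsize * softmax(log profile)`.
#' * Counts are NB with `Var = mu + nb_dispersion * mu^2`
#'   (`nb_dispersion = 0` is the Poisson limit).
#' * Covariates are cluster-linked: a binary mutation flag
#'   (`Bernoulli(mutation_assoc[subtype])`), exponential survival with
#'   per-subtype hazard (`hazard_by_cluster`), independent censoring with
#'   probability `censor_rate` (a censored sample is observed at a
#'   uniform fraction of its event time), and a categorical histology
#'   label whose per-subtype distribution is Dirichlet-drawn and
#'   concentrated on a subtype-matched level.
#'
#' Identical arguments and `seed` give bit-identical cohorts.
#'
#' @param n_genes genes per species.
#' @param n_orthologs one-to-one ortholog pairs (`<= n_genes`).
#' @param n_human,n_mouse sample counts.
#' @param k_true number of planted subtypes.
#' @param frac_marker fraction of ortholog genes that are markers of each
#'   subtype; `k_true * frac_marker` must be < 1 (disjoint marker sets).
#' @param log2_effect mean absolute log2 fold-change of marker genes.
#' @param nb_dispersion NB dispersion phi in `Var = mu + phi mu^2`.
#' @param lib_size_range length-2 positive vector (min, max) expected
#'   library size.
#' @param species_shift_sd s.d. of per-gene mouse log2 offsets.
#' @param mutation_assoc per-subtype mutation probability (recycled to
#'   `k_true`).
#' @param hazard_by_cluster per-subtype exponential hazard (recycled).
#' @param censor_rate independent censoring probability in [0, 1).
#' @param subtype_prob optional per-subtype sampling probabilities.
#' @param seed integer RNG seed.
#' @return list with `human_counts`, `mouse_counts` ([count_matrix()]),
#'   `ortholog_map`, `true_labels` (named, 1..k_true), `metadata`
#'   (data.frame: sample_id, species, subtype, mutation, time, event,
#'   histology), `marker_genes` (list per subtype, human ids),
#'   `marker_signs` (ground-truth effect direction per marker), and the
#'   generating parameters in `config`; class `humo_cohort`.
#' @export
simulate_cohort <- function(n_genes = 2500, n_orthologs = 2000,
                            n_human = 200, n_mouse = 80, k_true = 4,
                            frac_marker = 0.15, log2_effect = 1.5,
                            nb_dispersion = 0.1,
                            lib_size_range = c(2e5, 1e6),
                            species_shift_sd = 0.5,
                            mutation_assoc = c(0.5, rep(0.15, k_true - 1)),
                            hazard_by_cluster = default_hazards(k_true),
                            censor_rate = 0.3,
                            subtype_prob = NULL, seed = 1) {
  stopifnot(n_orthologs <= n_genes, k_true >= 1,
            frac_marker >= 0, frac_marker <= 1,
            log2_effect >= 0, nb_dispersion >= 0,
            length(lib_size_range) == 2, lib_size_range[1] > 0,
            lib_size_range[2] >= lib_size_range[1],
            species_shift_sd >= 0, censor_rate >= 0, censor_rate < 1)
  if (k_true * frac_marker >= 1)
    stop("k_true * frac_marker must be < 1: marker sets are disjoint ",
         "subsets of the orthologs")
  mutation_assoc <- rep_len(mutation_assoc, k_true)
  hazard_by_cluster <- rep_len(hazard_by_cluster, k_true)
  stopifnot(all(mutation_assoc >= 0 & mutation_assoc <= 1),
            all(hazard_by_cluster > 0))
  set.seed(seed)

  hg <- sprintf("HG%05d", seq_len(n_genes))
  mg <- sprintf("MG%05d", seq_len(n_genes))
  omap <- ortholog_map(hg[seq_len(n_orthologs)], mg[seq_len(n_orthologs)])

  # shared baseline (log2) for orthologs; species-private genes get their own
  base_orth <- stats::rnorm(n_orthologs, mean = 5, sd = 1.5)
  base_h <- c(base_orth, stats::rnorm(n_genes - n_orthologs, 5, 1.5))
  base_m <- c(base_orth, stats::rnorm(n_genes - n_orthologs, 5, 1.5))
  shift_m <- stats::rnorm(n_genes, 0, species_shift_sd)   # mouse offsets

  # disjoint marker blocks among orthologs, signed effects
  n_mark <- floor(frac_marker * n_orthologs)
  marker_idx <- if (n_mark > 0)
    split(sample(n_orthologs, n_mark * k_true),
          rep(seq_len(k_true), each = n_mark)) else
    rep(list(integer(0)), k_true)
  effect <- matrix(0, n_genes, k_true)
  marker_sign <- vector("list", k_true)
  for (s in seq_len(k_true)) {
    marker_sign[[s]] <- sample(c(-1, 1), n_mark, replace = TRUE)
    effect[marker_idx[[s]], s] <- log2_effect * marker_sign[[s]]
  }

  draw_species <- function(n_samp, base, is_mouse, prefix) {
    subtype <- if (is.null(subtype_prob))
      sample(k_true, n_samp, replace = TRUE) else
      sample(k_true, n_samp, replace = TRUE, prob = subtype_prob)
    lib <- stats::runif(n_samp, lib_size_range[1], lib_size_range[2])
    counts <- matrix(0, n_genes, n_samp)
    for (j in seq_len(n_samp)) {
      lp <- base + effect[, subtype[j]] + if (is_mouse) shift_m else 0
      w <- 2^lp
      mu <- lib[j] * w / sum(w)
      counts[, j] <- if (nb_dispersion > 0)
        stats::rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion) else
        stats::rpois(n_genes, mu)
    }
    dimnames(counts) <- list(if (is_mouse) mg else hg,
                             sprintf("%s%03d", prefix, seq_len(n_samp)))
    list(counts = counts, subtype = subtype)
  }
  h <- draw_species(n_human, base_h, FALSE, "HS")
  m <- draw_species(n_mouse, base_m, TRUE, "MS")

  sample_id <- c(colnames(h$counts), colnames(m$counts))
  subtype <- c(h$subtype, m$subtype)
  species <- rep(c("human", "mouse"), c(n_human, n_mouse))

  mutation <- stats::rbinom(length(subtype), 1, mutation_assoc[subtype])
  t_event <- stats::rexp(length(subtype), rate = hazard_by_cluster[subtype])
  censored <- stats::rbinom(length(subtype), 1, censor_rate) == 1
  time <- ifelse(censored, t_event * stats::runif(length(subtype)), t_event)
  event <- as.integer(!censored)

  # histology: per-subtype Dirichlet-drawn categorical distribution,
  # concentrated on a subtype-matched level
  levels_h <- c("well_differentiated", "inflamed", "steatotic", "ecm_rich")
  hist_prob <- t(vapply(seq_len(k_true), function(s) {
    alpha <- rep(1, length(levels_h))
    alpha[((s - 1) %% length(levels_h)) + 1] <- 8
    g <- stats::rgamma(length(levels_h), alpha)
    g / sum(g)
  }, numeric(length(levels_h))))
  histology <- vapply(subtype, function(s)
    sample(levels_h, 1, prob = hist_prob[s, ]), character(1))

  metadata <- data.frame(sample_id = sample_id, species = species,
                         subtype = subtype, mutation = mutation,
                         time = time, event = event, histology = histology,
                         stringsAsFactors = FALSE)
  structure(list(
    human_counts = count_matrix(h$counts, "human", "sim_human"),
    mouse_counts = count_matrix(m$counts, "mouse", "sim_mouse"),
    ortholog_map = omap,
    true_labels = stats::setNames(subtype, sample_id),
    metadata = metadata,
    marker_genes = lapply(marker_idx, function(i) hg[i]),
    marker_signs = lapply(seq_len(k_true), function(s)
      stats::setNames(marker_sign[[s]], hg[marker_idx[[s]]])),
    config = list(n_genes = n_genes, n_orthologs = n_orthologs,
                  n_human = n_human, n_mouse = n_mouse, k_true = k_true,
                  frac_marker = frac_marker, log2_effect = log2_effect,
                  nb_dispersion = nb_dispersion,
                  lib_size_range = lib_size_range,
                  species_shift_sd = species_shift_sd,
                  mutation_assoc = mutation_assoc,
                  hazard_by_cluster = hazard_by_cluster,
                  censor_rate = censor_rate, seed = seed)),
    class = "humo_cohort")
}

# cluster 2 is the good-prognosis cluster, mirroring the inflammation-low
# hazard contrast the analysis is meant to detect
default_hazards <- function(k_true) {
  h <- c(0.10, 0.05, 0.15, 0.20)
  rep_len(h, max(k_true, 1))[seq_len(k_true)]
}

#' @export
print.humo_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("humo_cohort: %d human + %d mouse samples, %d genes ",
                     "(%d orthologs), %d planted subtypes\n"),
              cfg$n_human, cfg$n_mouse, cfg$n_genes, cfg$n_orthologs,
              cfg$k_true))
  print(table(subtype = x$true_labels,
              species = x$metadata$species[match(names(x$true_labels),
                                                 x$metadata$sample_id)]))
  invisible(x)
}

#' Summary statistics of a simulated cohort
#'
#' Bookkeeping used to validate the generator: per-gene means/variances
#' (on raw counts, per species), per-sample library sizes, subtype label
#' counts, and a method-of-moments dispersion estimate per gene.
#'
#' @param cohort a `humo_cohort` from [simulate_cohort()].
#' @return list with `gene_stats` (data.frame: species, gene_id, mean,
#'   variance, dispersion_mom), `library_sizes` (named per sample),
#'   `label_counts` (table).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "humo_cohort"))
  per_species <- function(m, sp) {
    mu <- rowMeans(m)
    v <- apply(unclass(m), 1, stats::var)
    data.frame(species = sp, gene_id = rownames(m), mean = mu, variance = v,
               dispersion_mom = (v - mu) / mu^2,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  gene_stats <- rbind(per_species(cohort$human_counts, "human"),
                      per_species(cohort$mouse_counts, "mouse"))
  lib <- c(colSums(cohort$human_counts), colSums(cohort$mouse_counts))
  list(gene_stats = gene_stats, library_sizes = lib,
       label_counts = table(cohort$true_labels))
}

#' Write a simulated cohort to plain-text files
#'
#' Writes the two count matrices (TSV or MatrixMarket), the ortholog map,
#' the metadata table, and the generating parameters as JSON.
#'
#' @param cohort a `humo_cohort`.
#' @param dir output directory (created if needed).
#' @param format count-matrix format, `"tsv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tsv") ".tsv" else ".mtx"
  write_counts(cohort$human_counts, file.path(dir, paste0("human_counts", ext)),
               format)
  write_counts(cohort$mouse_counts, file.path(dir, paste0("mouse_counts", ext)),
               format)
  write_ortholog_map(cohort$ortholog_map, file.path(dir, "ortholog_map.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
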