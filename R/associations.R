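#' Fisher exact test with log odds ratio and Wald CI
#'
#' Two-sided exact p by the "probability mass <= observed" rule: the sum
#' of hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the observed table's probability (with a
#' small relative tolerance for float ties). The reported odds ratio is
#' the sample OR `ad/bc`, with the Haldane-Anscombe correction (+0.5 on
#' all four cells) applied only when some cell is zero; the 95% CI is
#' Wald on the log-odds scale, `logOR +/- 1.96 sqrt(sum(1/cell))`, on the
#' (possibly corrected) cells. The correction affects OR and CI but never
#' the exact p.
#'
#' @param tab 2x2 matrix (or `c(a, b, c, d)` row-wise) of non-negative
#'   integer counts, feature +/- in rows, group member/non-member in
#'   columns.
#' @return list with `odds_ratio`, `log_or`, `ci_low`, `ci_high` (log-OR
#'   scale), `p_value`, `corrected`; class `fisher_result`.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (sum(tab) == 0) stop("empty contingency table")
  p <- stats::fisher.test(tab)$p.value
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  se <- sqrt(sum(1 / tc))
  structure(list(odds_ratio = or, log_or = log(or),
                 ci_low = log(or) - 1.96 * se, ci_high = log(or) + 1.96 * se,
                 p_value = min(p, 1), corrected = corrected),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (logOR %.3f, 95%% CI [%.3f, %.3f]), p = %.4g%s\n",
              x$odds_ratio, x$log_or, x$ci_low, x$ci_high, x$p_value,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Cluster-by-feature Fisher association panel
#'
#' For each cluster and each feature, tests the one-vs-rest 2x2 table
#' (feature +/- x in-cluster/not) with [fisher_exact()], reproducing the
#' log-odds dot-and-bar panels relating clusters to histology features.
#' Binary/logical features are used as-is; categorical features are
#' binarized as "any vs `negative_level`". When a `species` column is
#' present in `meta` and `by_species = TRUE`, panels are computed per
#' species. Significance is flagged at p <= 0.05 (open/closed circle
#' convention); an optional BH adjustment across the panel is off by
#' default.
#'
#' @param labels a `cluster_assignment` (or named label vector).
#' @param meta data.frame with `sample_id` and the feature columns.
#' @param features character vector of feature column names.
#' @param negative_level value(s) of a categorical feature treated as
#'   feature-negative (default `"none"`).
#' @param by_species compute per-species panels when species is known.
#' @param adjust apply BH correction across the panel.
#' @return data.frame: `species`, `cluster`, `feature`, `a`-`d` cell
#'   counts, `odds_ratio`, `log_or`, `ci_low`, `ci_high`, `p_value`,
#'   `significant` (and `fdr` if `adjust`).
#' @export
cluster_feature_panel <- function(labels, meta, features,
                                  negative_level = "none",
                                  by_species = TRUE, adjust = FALSE) {
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  sp <- if (inherits(labels, "cluster_assignment")) labels$species else NULL
  meta <- meta[match(names(lab), meta$sample_id), , drop = FALSE]
  groups <- if (by_species && !is.null(sp) && !all(is.na(sp)))
    split(seq_along(lab), sp) else list(all = seq_along(lab))
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (f in features) {
      v <- meta[[f]][idx]
      if (all(is.na(v))) {
        warning("feature '", f, "' is all-missing; skipped")
        next
      }
      pos <- binarize_feature(v, negative_level)
      for (cl in sort(unique(lab[idx]))) {
        inc <- lab[idx] == cl
        ok <- !is.na(pos)
        tab <- matrix(c(sum(pos[ok] & inc[ok]), sum(pos[ok] & !inc[ok]),
                        sum(!pos[ok] & inc[ok]), sum(!pos[ok] & !inc[ok])),
                      2, 2, byrow = TRUE)
        fr <- fisher_exact(tab)
        rows[[length(rows) + 1]] <- data.frame(
          species = g, cluster = cl, feature = f,
          a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
          odds_ratio = fr$odds_ratio, log_or = fr$log_or,
          ci_low = fr$ci_low, ci_high = fr$ci_high, p_value = fr$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- (if (adjust) out$fdr else out$p_value) <= 0.05
  out
}

binarize_feature <- function(v, negative_level) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("numeric features must be 0/1")
    return(v == 1)
  }
  ifelse(is.na(v), NA, !(as.character(v) %in% negative_level))
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator `S(t) = prod_(t_i <= t) (1 - d_i/n_i)` for
#' each group, via the survival package.
#'
#' @param time positive survival/censoring times.
#' @param event 0/1 event indicators.
#' @param group group labels (a single group is permitted).
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_curves <- function(time, event, group = rep("all", length(time))) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  df <- data.frame(time = time, event = event, group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(df$group), length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, survival = s$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test across groups
#'
#' Standard log-rank: at each event time the observed events per group
#' are compared with their hypergeometric expectation; the statistic is
#' chi-squared with (groups - 1) degrees of freedom. Groups with no
#' at-risk subjects are dropped with a warning.
#'
#' @inheritParams km_curves
#' @return list with `statistic`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  df <- data.frame(time = time, event = event, group = as.character(group))
  tab <- table(df$group)
  if (any(tab == 0)) {
    warning("group(s) with zero at-risk dropped: ",
            paste(names(tab)[tab == 0], collapse = ", "))
    df <- df[df$group %in% names(tab)[tab > 0], ]
  }
  g <- length(unique(df$group))
  if (g < 2) stop("at least 2 non-empty groups required")
  if (sum(df$event) == 0) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- g - 1
  list(statistic = unname(sd$chisq), df = dfree,
       p_value = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE),
       n_groups = g)
}
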