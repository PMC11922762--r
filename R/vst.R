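#' Median-of-ratios size factors
#'
#' Per-sample scale factors estimated against a geometric-mean
#' pseudo-reference: for each gene with strictly positive counts in every
#' sample, the ratio of that sample's count to the gene's geometric mean is
#' taken, and the factor is the median ratio. Factors are not rescaled
#' further.
#'
#' @param counts genes x samples count matrix ([count_matrix()] or plain).
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has strictly positive counts in all samples; ",
         "size factors are undefined (consider a pseudo-reference fallback)")
  lg <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lg)                       # log geometric mean
  sf <- apply(exp(lg - ref), 2, stats::median)
  names(sf) <- colnames(m)
  sf
}

#' Fit the dispersion-mean trend alpha(mu) = a1/mu + a0
#'
#' Gene-wise negative-binomial dispersions are estimated by method of
#' moments on size-factor-normalized counts, phi_g = (var_g - mean_g) /
#' mean_g^2, and the trend is fitted by least squares of phi_g on 1/mean_g
#' over genes with mean >= 1 and positive variance, followed by one round
#' of outlier trimming (residuals beyond 2 x IQR dropped) and a refit.
#' Gene-wise estimates enter the fit unclamped so that sampling noise
#' around phi = 0 cancels rather than biasing the intercept; only the
#' fitted coefficients are clamped (a0 >= 1e-4, a1 >= 0).
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors from [size_factors()].
#' @return list with elements `a0`, `a1`, class `dispersion_trend`.
#' @export
fit_dispersion_trend <- function(counts, sf) {
  m <- sweep(unclass(counts), 2, sf, "/")
  if (ncol(m) < 2) stop("at least 2 samples required to estimate dispersion")
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  phi <- (v - mu) / mu^2
  use <- is.finite(phi) & mu >= 1 & v > 0
  if (sum(use) < 50) {
    warning("fewer than 50 usable genes for the dispersion trend; ",
            "falling back to a constant dispersion")
    hi <- is.finite(phi) & mu >= 10 & phi > 0
    if (!any(hi))
      stop("no dispersed genes with mean >= 10; cannot estimate dispersion")
    return(structure(list(a0 = max(stats::median(phi[hi]), 1e-4), a1 = 0),
                     class = "dispersion_trend"))
  }
  x <- 1 / mu[use]
  y <- phi[use]
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- fit$residuals
  iqr <- stats::IQR(r)
  keep <- abs(r - stats::median(r)) <= 2 * iqr
  if (sum(keep) >= 50) fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
  a0 <- max(unname(fit$coefficients[1]), 1e-4)
  a1 <- max(unname(fit$coefficients[2]), 0)
  structure(list(a0 = a0, a1 = a1), class = "dispersion_trend")
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("dispersion trend alpha(mu) = %.4g/mu + %.4g\n", x$a1, x$a0))
  invisible(x)
}

#' Closed-form variance-stabilizing transform
#'
#' For normalized counts q = count/size factor and the fitted trend
#' alpha(mu) = a1/mu + a0, the transform is
#' \deqn{\log_2\frac{1 + a_1 + 2 a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0}}
#' which is strictly increasing in q, behaves like sqrt(q) at low counts
#' and approaches log2(q) at high counts (so a doubling of q adds 1).
#' q = 0 is in the domain.
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors from [size_factors()].
#' @param trend a `dispersion_trend` from [fit_dispersion_trend()].
#' @return genes x samples numeric matrix with attribute
#'   `transform = "vst"`.
#' @export
vst_transform <- function(counts, sf, trend) {
  stopifnot(inherits(trend, "dispersion_trend"))
  q <- sweep(unclass(counts), 2, sf, "/")
  out <- vst_values(q, trend$a0, trend$a1)
  dimnames(out) <- dimnames(q)
  attr(out, "transform") <- "vst"
  out
}

# the scalar/elementwise closed form; exported for property checks
#' Evaluate the VST closed form on normalized counts
#' @param q normalized counts (any numeric array), q >= 0.
#' @param a0 asymptotic dispersion (> 0).
#' @param a1 extra-Poisson term (>= 0).
#' @return same shape as `q`.
#' @export
vst_values <- function(q, a0, a1) {
  stopifnot(a0 > 0, a1 >= 0, all(q >= 0))
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

#' Centre an expression matrix within each sample
#'
#' Subtracts each sample's (column's) mean across genes, so every sample
#' mean is 0; applied after ortholog harmonization so the human and mouse
#' sample means are comparable on the same genes. Idempotent.
#'
#' @param e genes x samples expression matrix (transform tag `"vst"` or
#'   untagged).
#' @return the centred matrix, attribute `transform = "vst_centered"`.
#' @export
center_within_sample <- function(e) {
  out <- sweep(unclass(e), 2, colMeans(e), "-")
  attr(out, "transform") <- "vst_centered"
  out
}

#' One-call per-species normalization
#'
#' Convenience wrapper running [size_factors()], [fit_dispersion_trend()]
#' and [vst_transform()] on one cohort.
#'
#' @param counts genes x samples count matrix.
#' @return list with `vst` (matrix), `size_factors`, `trend`.
#' @export
normalize_counts <- function(counts) {
  sf <- size_factors(counts)
  trend <- fit_dispersion_trend(counts, sf)
  list(vst = vst_transform(counts, sf, trend), size_factors = sf,
       trend = trend)
}
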