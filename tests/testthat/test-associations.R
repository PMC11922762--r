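test_that("Fisher results match hand-worked tables", {
  # [[3,0],[0,3]]: 2 * C(3,3)C(3,0)/C(6,3) = 2/20
  r <- fisher_exact(matrix(c(3, 0, 0, 3), 2, 2))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_true(r$corrected)          # zero cells -> Haldane-Anscombe OR
  expect_equal(r$odds_ratio, (3.5 * 3.5) / (0.5 * 0.5))

  # the printed CTNNB1-by-cluster-1 contingency: OR = 57*222/(31*61)
  r2 <- fisher_exact(matrix(c(57, 31, 61, 222), 2, 2, byrow = TRUE))
  expect_equal(r2$odds_ratio, (57 * 222) / (31 * 61), tolerance = 1e-12)
  expect_equal(r2$odds_ratio, 6.69, tolerance = 0.001)
  expect_false(r2$corrected)
  expect_lt(r2$p_value, 1e-10)
  expect_true(r2$ci_low <= r2$log_or && r2$log_or <= r2$ci_high)

  # balanced table: OR 1, logOR 0, p 1
  r3 <- fisher_exact(matrix(5, 2, 2))
  expect_equal(r3$odds_ratio, 1)
  expect_equal(r3$log_or, 0)
  expect_equal(r3$p_value, 1)

  expect_error(fisher_exact(matrix(0, 2, 2)), "empty")
})

test_that("Fisher p equals hypergeometric enumeration on small tables", {
  # exhaustive over a lattice of totals, spot-checking the full rule
  set.seed(1)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    cc <- sample(0:(n - a - b), 1); d <- n - a - b - cc
    tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("OR is transpose-invariant and logOR negates under row swap", {
  set.seed(2)
  for (i in 1:20) {
    tab <- matrix(sample(1:30, 4, TRUE), 2, 2)
    r <- fisher_exact(tab)
    expect_equal(fisher_exact(t(tab))$odds_ratio, r$odds_ratio)
    expect_equal(fisher_exact(tab[2:1, ])$log_or, -r$log_or)
  }
})

test_that("the feature panel flags aliased features and keeps type-I error", {
  lab <- structure(list(labels = setNames(rep(1:3, each = 30),
                                          sprintf("s%02d", 1:90)),
                        species = setNames(rep(c("human", "mouse"), 45),
                                           sprintf("s%02d", 1:90))),
                   class = "cluster_assignment")
  meta <- data.frame(sample_id = sprintf("s%02d", 1:90),
                     aliased = rep(c(1, 0, 0), each = 30),
                     stringsAsFactors = FALSE)
  pan <- cluster_feature_panel(lab, meta, "aliased", by_species = FALSE)
  expect_equal(nrow(pan), 3)
  best <- pan[which.max(pan$log_or), ]
  expect_equal(best$cluster, 1)
  expect_true(best$significant)
  expect_equal(best$p_value, min(pan$p_value))

  # per-species grouping produces one panel per species
  pan2 <- cluster_feature_panel(lab, meta, "aliased", by_species = TRUE)
  expect_setequal(unique(pan2$species), c("human", "mouse"))

  # categorical binarization: any vs "none"
  meta$hist <- rep(c("none", "focal", "abundant"), 30)
  pan3 <- cluster_feature_panel(lab, meta, "hist", by_species = FALSE)
  expect_equal(pan3$a + pan3$c, rep(30, 3))
  expect_equal(pan3$a[1] + pan3$b[1], 60)    # 60 of 90 are non-"none"

  # all-missing feature is skipped with a warning
  meta$gone <- NA
  expect_warning(cluster_feature_panel(lab, meta, c("aliased", "gone"),
                                       by_species = FALSE), "gone")
})

test_that("independent features keep the nominal type-I error rate", {
  set.seed(3)
  lab <- structure(list(labels = setNames(sample(1:2, 60, TRUE),
                                          sprintf("s%02d", 1:60)),
                        species = setNames(rep(NA_character_, 60),
                                           sprintf("s%02d", 1:60))),
                   class = "cluster_assignment")
  hits <- 0; total <- 0
  for (i in 1:500) {
    meta <- data.frame(sample_id = sprintf("s%02d", 1:60),
                       f = rbinom(60, 1, 0.5))
    pan <- cluster_feature_panel(lab, meta, "f", by_species = FALSE)
    hits <- hits + sum(pan$p_value <= 0.05)
    total <- total + nrow(pan)
  }
  # exact tests are conservative; the rate must not exceed ~0.05
  expect_lt(hits / total, 0.06)
  expect_gt(hits / total, 0.005)
})

test_that("Kaplan-Meier estimates match the product-limit by hand", {
  km <- km_curves(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))
  expect_equal(km$n_risk, c(2, 1))
  # all censored: S stays at 1
  km2 <- km_curves(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  # with no censoring the KM equals the empirical survival function
  set.seed(4)
  tt <- rexp(40)
  km3 <- km_curves(tt, rep(1, 40))
  emp <- vapply(km3$time, function(t) mean(tt > t), numeric(1))
  expect_equal(km3$survival, emp, tolerance = 1e-12)
})

test_that("early censoring lifts the survival curve at scale", {
  # censoring an individual before their (unobserved) event removes
  # deaths, so at large n the censored-data KM sits on or above the
  # full-data KM across the time range
  set.seed(5)
  n <- 1000
  tt <- rexp(n, 0.3)
  cens <- rbinom(n, 1, 0.5) == 1
  tobs <- ifelse(cens, tt * runif(n), tt)
  km_full <- km_curves(tt, rep(1, n))
  km_cens <- km_curves(tobs, as.integer(!cens))
  s_full <- stats::stepfun(km_full$time, c(1, km_full$survival))
  s_cens <- stats::stepfun(km_cens$time, c(1, km_cens$survival))
  grid <- quantile(tt, seq(0.1, 0.9, by = 0.1))
  expect_true(all(s_cens(grid) >= s_full(grid) - 0.01))
})

test_that("log-rank matches identities, power and permutation null", {
  # duplicated group: O = E exactly
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 0, 1)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 1)

  # power: hazard ratio 3 with n = 200/arm rejects nearly always
  set.seed(6)
  rej <- mean(replicate(200, {
    t1 <- rexp(200, 1); t2 <- rexp(200, 3)
    logrank_test(c(t1, t2), rep(1, 400),
                 rep(c("a", "b"), each = 200))$p_value <= 0.05
  }))
  expect_gte(rej, 0.95)

  # permutation null: p approximately uniform
  set.seed(7)
  tt <- rexp(60); ev <- rbinom(60, 1, 0.8)
  ps <- replicate(500,
    logrank_test(tt, ev, sample(rep(c("a", "b"), 30)))$p_value)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "events")
})
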