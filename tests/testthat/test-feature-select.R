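make_tables <- function(n = 20, seed = 1) {
  # manual table plus variants: a volume proxy that erosion strictly
  # decreases, a contour-stable feature, and an independently re-drawn one
  set.seed(seed)
  vol <- runif(n, 50, 500)
  stable <- rnorm(n)
  indep <- rnorm(n)
  manual <- data.frame(volume = vol, stable = stable, indep = indep)
  rownames(manual) <- sprintf("L%02d", seq_len(n))
  variant <- function(shrink) {
    tb <- data.frame(volume = vol * shrink, stable = stable,
                     indep = rnorm(n))
    rownames(tb) <- rownames(manual)
    tb
  }
  list(manual = manual, eroded = variant(0.8), dilated = variant(1.25),
       jittered = variant(runif(n, 0.95, 1.05)))
}

test_that("the contour-dependence filter drops volume proxies and keeps stable features", {
  tabs <- make_tables()
  res <- filter_contour_dependent(tabs, alpha = 0.10)
  expect_true("volume" %in% res$dropped)
  expect_true("stable" %in% res$kept)
  # all-zero differences give p = 1 by convention
  expect_equal(unname(res$min_p["stable"]), 1)
})

test_that("the smallest attainable signed-rank p at n = 6 is 2/2^6", {
  tabs <- lapply(make_tables(), function(tb) tb[1:6, , drop = FALSE])
  res <- filter_contour_dependent(tabs, alpha = 0.10)
  # erosion shifts the volume proxy one-signed for all six lesions
  expect_equal(unname(res$min_p["volume"]), 2 / 2^6, tolerance = 1e-12)
  expect_true("volume" %in% res$dropped)
})

test_that("the contour filter validates alignment and honours exemptions", {
  tabs <- make_tables()
  bad <- tabs
  rownames(bad$eroded) <- rev(rownames(bad$eroded))
  expect_error(filter_contour_dependent(bad), "misaligned")
  expect_error(filter_contour_dependent(tabs["eroded"]), "at least 2")
  expect_error(filter_contour_dependent(unname(tabs)), "manual")
  res <- filter_contour_dependent(tabs, exempt = "volume")
  expect_true("volume" %in% res$kept)
})

test_that("the low-variability filter drops constants and near-constants", {
  tb <- data.frame(const = rep(1, 30),
                   binary = rep(c(0, 1), 15),       # 2 unique values
                   tiny_cv = 1000 + rnorm(30, 0, 1e-4),
                   zscored = rnorm(30),
                   normal = rnorm(30, 5, 2))
  res <- filter_low_variability(tb)
  expect_setequal(res$dropped, c("const", "binary", "tiny_cv"))
  expect_setequal(res$kept, c("zscored", "normal"))
})

test_that("redundancy clustering keeps one representative per correlated cluster", {
  set.seed(4)
  n <- 80
  x <- rnorm(n)
  tb <- data.frame(a_raw = x, b_exp = exp(x), c_indep = rnorm(n))
  t_ev <- rexp(n, exp(x) / 10)
  time <- pmin(t_ev, 15)
  event <- as.integer(t_ev <= 15)
  res <- cluster_correlated(tb, time, event, rho_threshold = 0.8)
  # |Spearman| = 1 for x vs exp(x): same cluster, one representative
  expect_length(res$representatives, 2)
  expect_true("c_indep" %in% res$representatives)
  expect_true(sum(c("a_raw", "b_exp") %in% res$representatives) == 1)
  expect_equal(unname(res$cluster_map["a_raw"]), unname(res$cluster_map["b_exp"]))

  # identical columns: tie broken to the lexicographically smallest name
  tb2 <- data.frame(zz = x, aa = x)
  res2 <- cluster_correlated(tb2, time, event)
  expect_equal(res2$representatives, "aa")
})

test_that("cluster count matches the dendrogram cut on the 3-feature example", {
  # pairwise |rho| = {0.9, 0.9, 0.3}: complete linkage at threshold 0.8 keeps
  # the 0.3 pair apart -> exactly 2 clusters
  n <- 400
  set.seed(10)
  # construct ranks directly to pin the Spearman correlations
  u <- seq_len(n)
  mix <- function(r, rho) {
    # blend of the shared ranking and an independent one, tuned to |rho|
    k <- ceiling((1 - rho) * n / 2)
    swap <- sample(n, k)
    r2 <- r
    r2[swap] <- sample(r[swap])
    r2
  }
  a <- u
  b <- mix(u, 0.995)
  c_ <- sample(u)
  tb <- data.frame(a = a, b = b, c = c_)
  rho <- abs(cor(tb, method = "spearman"))
  expect_gt(rho["a", "b"], 0.8)
  expect_lt(rho["a", "c"], 0.8)
  time <- rexp(n); event <- rbinom(n, 1, 0.5)
  res <- cluster_correlated(tb, time, event)
  expect_length(res$representatives, 2)
})

test_that("the univariate filter keeps true predictors and is alpha-calibrated", {
  set.seed(77)
  n <- 300
  lp <- rnorm(n)
  t_ev <- rexp(n, exp(lp) / 10)
  time <- pmin(t_ev, 15)
  event <- as.integer(t_ev <= 15)
  res <- univariate_filter(data.frame(true_lp = lp), time, event)
  expect_true("true_lp" %in% res$kept)

  # type-I calibration: an independent noise feature is kept w.p. ~ alpha
  kept <- 0L
  n_rep <- 200
  for (b in seq_len(n_rep)) {
    noise <- rnorm(n)
    r <- univariate_filter(data.frame(z = noise), time, event, alpha = 0.05)
    if ("z" %in% r$kept) kept <- kept + 1L
  }
  p_hat <- kept / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(p_hat - 0.05), 3 * se)

  # alpha = 1 keeps everything fittable
  r1 <- univariate_filter(data.frame(a = lp, b = rnorm(n)), time, event,
                          alpha = 1)
  expect_setequal(r1$kept, c("a", "b"))
})

test_that("non-convergent univariate fits are dropped with a warning", {
  n <- 40
  time <- seq_len(n)
  event <- rep(1L, n)
  sep <- -seq_len(n)  # perfectly orders the times: monotone likelihood
  expect_warning(
    res <- univariate_filter(data.frame(sep = sep + 0), time, event),
    "failed for feature sep")
  expect_true("sep" %in% res$dropped)
  expect_error(univariate_filter(data.frame(a = 1:4), 1:4, c(1, 0, 0, 0)),
               "2 events")
})

test_that("run_feature_elimination reports a partition and audits each stage", {
  set.seed(12)
  n <- 60
  tabs <- make_tables(n = n, seed = 12)
  # add a duplicated informative feature pair and a constant
  lp <- rnorm(n)
  for (v in names(tabs)) {
    tabs[[v]]$sig_a <- lp
    tabs[[v]]$sig_b <- lp * 2 + 1   # |Spearman| = 1 with sig_a
    tabs[[v]]$flat <- 7
  }
  t_ev <- rexp(n, exp(1.5 * lp) / 8)
  time <- pmin(t_ev, 12)
  event <- as.integer(t_ev <= 12)
  covs <- data.frame(kps_high = rbinom(n, 1, 0.5), age = rnorm(n, 60, 10))
  rownames(covs) <- rownames(tabs$manual)

  rep_ <- suppressWarnings(run_feature_elimination(
    tabs, covs, time, event))
  expect_s3_class(rep_, "elimination_report")
  parts <- c(rep_$dropped_contour_dependent, rep_$dropped_low_variability,
             rep_$dropped_redundant, rep_$dropped_univariate, rep_$surviving)
  expect_setequal(parts, rep_$input_features)
  expect_equal(anyDuplicated(parts), 0L)
  expect_true("volume" %in% rep_$dropped_contour_dependent)
  expect_true("flat" %in% rep_$dropped_low_variability)
  expect_true(any(c("sig_a", "sig_b") %in% rep_$dropped_redundant))
  expect_true(any(c("sig_a", "sig_b") %in% rep_$surviving))
  # covariates bypass the contour and clustering stages
  expect_false(any(c("kps_high", "age") %in%
                     c(rep_$dropped_contour_dependent, rep_$dropped_redundant,
                       rep_$dropped_low_variability)))
  expect_true(all(c("kps_high", "age") %in%
                    c(rep_$dropped_univariate, rep_$surviving)))
})
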