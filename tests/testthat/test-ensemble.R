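# Small purely tabular modeling problem (no images): 60 lesions, 20 patients,
# one informative feature among noise, identity contour variants.
tabular_problem <- function(seed = 21, n_pat = 20, lesions_per = 3,
                            beta = 1.5) {
  set.seed(seed)
  n <- n_pat * lesions_per
  meta <- data.frame(lesion_id = sprintf("L%03d", seq_len(n)),
                     patient_id = rep(sprintf("P%02d", seq_len(n_pat)),
                                      each = lesions_per),
                     stringsAsFactors = FALSE)
  tab <- data.frame(sig = rnorm(n), matrix(rnorm(n * 5), n, 5))
  colnames(tab)[-1] <- paste0("noise", 1:5)
  rownames(tab) <- meta$lesion_id
  lp <- beta * tab$sig
  t_ev <- rexp(n, exp(lp) / 15)
  cens <- runif(n, 6, 30)
  outcomes <- data.frame(lesion_id = meta$lesion_id,
                         time_months = pmin(t_ev, cens),
                         event = as.integer(t_ev <= cens),
                         stringsAsFactors = FALSE)
  list(tables = identity_variants(tab), meta = meta, outcomes = outcomes)
}

test_that("split plans are patient-disjoint, seeded, and sized by train_frac", {
  ids <- sprintf("P%02d", 1:23)
  plan <- make_split_plan(ids, n_outer = 8, n_inner = 6, seed = 5)
  expect_s3_class(plan, "split_plan")
  expect_length(plan, 8)
  for (sp in plan) {
    expect_length(intersect(sp$train_patients, sp$test_patients), 0)
    expect_setequal(c(sp$train_patients, sp$test_patients), ids)
    expect_equal(length(sp$train_patients), round(0.8 * 23))
    expect_length(sp$inner, 6)
    for (inn in sp$inner) {
      expect_length(intersect(inn$train, inn$validation), 0)
      expect_setequal(c(inn$train, inn$validation), sp$train_patients)
    }
  }
  expect_equal(make_split_plan(ids, 3, 2, seed = 9),
               make_split_plan(ids, 3, 2, seed = 9))
  expect_error(make_split_plan(sprintf("P%d", 1:4)), "at least 5")
  expect_error(make_split_plan(ids, train_frac = 1.2), "train_frac")
})

test_that("trimmed mean excludes only scores strictly beyond trim_k SD", {
  expect_equal(trimmed_mean_risk(c(0, 0, 0, 0, 0, 9)), 0.0)
  expect_equal(trimmed_mean_risk(c(1, 1, 1, 1, 10)), 2.8)
  expect_equal(trimmed_mean_risk(rep(3, 4)), 3)       # zero SD
  expect_equal(trimmed_mean_risk(5), 5)
  expect_error(trimmed_mean_risk(numeric(0)), "empty")
})

test_that("run_nested_cv recovers a tabular signal and reports coherently", {
  pr <- tabular_problem()
  plan <- make_split_plan(unique(pr$meta$patient_id), n_outer = 5,
                          n_inner = 5, seed = 3)
  res <- run_nested_cv(pr$tables, covariates = NULL, outcomes = pr$outcomes,
                       meta = pr$meta, plan = plan,
                       feature_groups = "radiomic",
                       config = run_config(n_outer = 5, n_inner = 5))
  r <- res$report
  expect_length(r$outer_c_index, 5)
  expect_equal(r$n_outer_evaluated, sum(!is.na(r$outer_c_index)))
  expect_gte(r$member_success_fraction, 0)
  expect_lte(r$member_success_fraction, 1)
  expect_gt(r$mean_c_index, 0.5)
  expect_true("sig" %in% names(r$feature_inclusion))
  expect_true(all(unlist(r$feature_inclusion) <= 1))
  hr <- r$hazard_ratios
  expect_true("sig" %in% names(hr))
  expect_gt(hr$sig$mean, 1)  # hazardous direction, per training SD
  for (e in res$ensembles) {
    if (is.null(e)) next
    expect_s3_class(e, "ensemble_model")
    for (m in e$members) expect_s3_class(m, "cox_model")
  }
})

test_that("training never reads outer-test outcomes (byte-identical ensembles)", {
  pr <- tabular_problem(seed = 33)
  plan <- make_split_plan(unique(pr$meta$patient_id), n_outer = 2,
                          n_inner = 4, seed = 8)
  cfg <- run_config(n_outer = 2, n_inner = 4)
  for (o in 1:2) {
    single <- structure(plan[o], class = "split_plan")
    test_rows <- pr$meta$patient_id %in% plan[[o]]$test_patients
    scrambled <- pr$outcomes
    scrambled$time_months[test_rows] <- rev(scrambled$time_months[test_rows]) + 0.37
    scrambled$event[test_rows] <- 1L - scrambled$event[test_rows]
    r1 <- run_nested_cv(pr$tables, NULL, pr$outcomes, pr$meta, single,
                        feature_groups = "radiomic", config = cfg)
    r2 <- run_nested_cv(pr$tables, NULL, scrambled, pr$meta, single,
                        feature_groups = "radiomic", config = cfg)
    f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
    write_ensembles(r1$ensembles, f1)
    write_ensembles(r2$ensembles, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("external validation uses frozen standardization and skips NULLs", {
  set.seed(6)
  n <- 100
  X <- data.frame(f = rnorm(n, 50, 10))
  lp <- 0.08 * X$f
  t_ev <- rexp(n, exp(lp - 4))
  time <- pmin(t_ev, 12); event <- as.integer(t_ev <= 12)
  m <- fit_cox(X, time, event)
  ens <- structure(list(members = list(m), trim_k = 2, outer_split = 1L),
                   class = "ensemble_model")
  # external data on a shifted scale: frozen (center, scale) must be reused
  Xe <- data.frame(f = rnorm(80, 80, 10))
  sc <- risk_score(m, Xe)
  expect_equal(sc, m$coef[1] * (Xe$f - m$center[1]) / m$scale[1])
  lpe <- 0.08 * Xe$f
  te <- rexp(80, exp(lpe - 4))
  oute <- data.frame(time_months = pmin(te, 12),
                     event = as.integer(te <= 12))
  ev <- external_validate(list(NULL, ens), Xe, oute)
  expect_length(ev$per_ensemble_c, 1)
  expect_gt(ev$mean_c, 0.5)
  expect_error(external_validate(list(NULL), Xe, oute), "no trained ensembles")
})

test_that("stratify_and_test splits at the median and its null p is uniform", {
  set.seed(14)
  n <- 40
  time <- rexp(n, 0.08)
  event <- rbinom(n, 1, 0.7)
  scores <- rnorm(n)
  st <- stratify_and_test(scores, time, event)
  expect_equal(st$threshold, median(scores))
  expect_equal(st$n_high + st$n_low, n)
  expect_s3_class(st$km_high, "km_curve")
  expect_true(st$logrank$p >= 0 && st$logrank$p <= 1)
  expect_error(stratify_and_test(c(1, 2, 3), 1:3, c(1, 1, 1)), "at least 2")

  # outcome-independent scores: log-rank p ~ Uniform(0,1) across 200 seeds
  ps <- vapply(1:200, function(b) {
    set.seed(1000 + b)
    tt <- rexp(n, 0.08); ee <- rbinom(n, 1, 0.7); ss <- rnorm(n)
    stratify_and_test(ss, tt, ee)$logrank$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
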