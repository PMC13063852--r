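test_that("run_config validates and stores every tunable", {
  cfg <- run_config()
  expect_equal(cfg$margin_mm, 3.0)
  expect_equal(cfg$perturb_mm, 1.0)
  expect_equal(cfg$bin_width, 0.25)
  expect_equal(cfg$alpha_contour, 0.10)
  expect_equal(cfg$alpha_univ, 0.05)
  expect_equal(cfg$rho_threshold, 0.8)
  expect_equal(cfg$n_outer, 30)
  expect_equal(cfg$n_inner, 30)
  expect_equal(cfg$trim_k, 2.0)
  expect_equal(cfg$max_features, 4)
  expect_error(run_config(margin_mm = -3))
  expect_error(run_config(train_frac = 1))
  expect_error(run_config(feature_groups = "genomic"))
})

test_that("reports are bit-stable under key permutation", {
  a <- list(zeta = 1.25, alpha = list(c = 3L, b = list(x = 1, a = 2)),
            mid = "s")
  b <- list(mid = "s", alpha = list(b = list(a = 2, x = 1), c = 3L),
            zeta = 1.25)
  fa <- tempfile(fileext = ".json"); fb <- tempfile(fileext = ".json")
  write_report(a, fa)
  write_report(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  r <- load_report(fa)
  expect_equal(r$zeta, 1.25)
  expect_equal(r$alpha$b$a, 2)
  expect_error(load_report(tempfile()), "not found")
})

test_that("event_rate_percent reproduces cohort-table percentages", {
  expect_equal(event_rate_percent(72, 517), 13.9)
  expect_equal(event_rate_percent(40, 179), 22.3)
  expect_equal(event_rate_percent(33, 130), 25.4)
  expect_error(event_rate_percent(1, 0), "> 0")
})

test_that("generated cohorts load back through the manifest with validation", {
  tc <- tiny_cohort()
  man <- tc$manifest
  expect_s3_class(man, "cohort_manifest")
  expect_true(all(file.exists(man$lesions$image)))
  expect_equal(nrow(man$outcomes), nrow(man$lesions))
  expect_error(generate_cohort(tc$config, tc$dir), "already exists")

  # specific validation errors
  m <- jsonlite::read_json(file.path(tc$dir, "manifest.json"),
                           simplifyVector = FALSE)
  dup <- m
  dup$lesions[[2]]$lesion_id <- dup$lesions[[1]]$lesion_id
  p_dup <- tempfile(fileext = ".json")
  jsonlite::write_json(dup, p_dup, auto_unbox = TRUE)
  expect_error(load_manifest(p_dup), "duplicate lesion_id")

  mis <- m
  mis$lesions[[1]]$gtv <- file.path(tc$dir, "volumes", "nope.nii.gz")
  p_mis <- tempfile(fileext = ".json")
  jsonlite::write_json(mis, p_mis, auto_unbox = TRUE)
  expect_error(load_manifest(p_mis), "missing file")

  orph <- m
  out_csv <- utils::read.csv(m$outcomes_csv)
  p_out <- tempfile(fileext = ".csv")
  utils::write.csv(out_csv[-1, ], p_out, row.names = FALSE)
  orph$outcomes_csv <- p_out
  p_orph <- tempfile(fileext = ".json")
  jsonlite::write_json(orph, p_orph, auto_unbox = TRUE)
  expect_error(load_manifest(p_orph), "without outcome row")

  expect_error(load_manifest(tempfile()), "not found")
})

test_that("disk and in-memory extraction agree on the deterministic variants", {
  tc <- tiny_cohort()
  cfg <- run_config()
  ds_mem <- suppressWarnings(build_feature_dataset(tc$config, cfg))
  ds_disk <- suppressWarnings(extract_manifest_features(tc$manifest, cfg))
  common <- intersect(colnames(ds_mem$variant_tables$manual),
                      colnames(ds_disk$variant_tables$manual))
  expect_gt(length(common), 50)
  for (v in c("manual", "eroded", "dilated")) {
    expect_equal(ds_disk$variant_tables[[v]][, common],
                 ds_mem$variant_tables[[v]][, common], tolerance = 1e-4)
  }
  expect_equal(ds_disk$covariates$BED10, ds_mem$covariates$BED10,
               tolerance = 1e-6)
  expect_equal(ds_disk$covariates$kps_high, ds_mem$covariates$kps_high)
  expect_equal(ds_disk$outcomes$time_months, ds_mem$outcomes$time_months,
               tolerance = 1e-9)
})

test_that("lesion_variant_features returns aligned rows for all four variants", {
  cfg <- synthetic_config()
  sim <- simulate_lesion_image(toy_latent(0.4, cfg), cfg)
  rows <- lesion_variant_features(sim$image, sim$gtv, sim$brain,
                                  lesion_id = "L0001", jitter_seed = 3)
  expect_named(rows, c("manual", "eroded", "dilated", "jittered"))
  nm <- names(rows$manual)
  for (v in rows) expect_identical(names(v), nm)
  vol <- "GTV_original_shape_VoxelVolume_mm3"
  expect_lt(rows$eroded[[vol]], rows$manual[[vol]])
  expect_gt(rows$dilated[[vol]], rows$manual[[vol]])
})

test_that("run_all caches stages and reruns only downstream of a corruption", {
  tc <- tiny_cohort()
  run_dir <- file.path(tempdir(), "tiny_run")
  unlink(run_dir, recursive = TRUE)
  cfg <- run_config(n_outer = 2, n_inner = 2, seed = 2)
  r1 <- suppressWarnings(run_all(tc$manifest, cfg, run_dir))
  expect_setequal(r1$stages_run, c("extract", "train"))
  expect_true(file.exists(r1$report_path))
  expect_true(file.exists(r1$ensembles_path))
  expect_length(r1$report$outer_c_index, 2)

  r2 <- suppressWarnings(run_all(tc$manifest, cfg, run_dir))
  expect_length(r2$stages_run, 0)

  # corrupt one extracted feature table: only training reruns
  fp <- r1$feature_paths[1]
  tb <- utils::read.csv(fp, row.names = 1, check.names = FALSE)
  tb[1, 1] <- tb[1, 1] + 1
  utils::write.csv(tb, fp)
  r3 <- suppressWarnings(run_all(tc$manifest, cfg, run_dir))
  expect_equal(r3$stages_run, "train")

  # different config: everything reruns
  cfg2 <- run_config(n_outer = 2, n_inner = 2, seed = 2, bin_width = 0.5)
  r4 <- suppressWarnings(run_all(tc$manifest, cfg2, run_dir))
  expect_setequal(r4$stages_run, c("extract", "train"))
})

test_that("serialized ensembles reload with frozen member parameters", {
  set.seed(2)
  X <- data.frame(f = rnorm(60), g = rnorm(60))
  t_ev <- rexp(60, exp(X$f) / 10)
  m <- fit_cox(X, pmin(t_ev, 12), as.integer(t_ev <= 12), split_id = "o1/i1")
  ens <- structure(list(members = list(m), trim_k = 2, outer_split = 1L),
                   class = "ensemble_model")
  p <- tempfile(fileext = ".json")
  write_ensembles(list(ens, NULL), p)
  back <- jsonlite::read_json(p, simplifyVector = FALSE)$ensembles
  expect_length(back, 2)
  expect_null(back[[2]])
  mb <- back[[1]]$members[[1]]
  expect_equal(unlist(mb$features), m$features)
  expect_equal(unlist(mb$coef), m$coef, tolerance = 1e-12)
  expect_equal(unlist(mb$center), m$center, tolerance = 1e-12)
  expect_equal(unlist(mb$scale), m$scale, tolerance = 1e-12)
})
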