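# Shared, lazily built datasets, memoized for the duration of the test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# Recovery-study cohort: ~200 lesions whose peritumoral infiltration carries
# the planted outcome signal (log-hazard 3 per unit infiltration, i.e. a true
# hazard ratio above 2 per SD of the realized margin feature).
recovery_config <- function(beta_infiltration = 3, seed = 101) {
  synthetic_config(n_patients = 85,
                   true_betas = c(infiltration = beta_infiltration),
                   seed = seed)
}

recovery_dataset <- function() {
  memo("recovery_dataset", function() {
    ds <- suppressWarnings(build_feature_dataset(recovery_config(), run_config()))
    plan <- make_split_plan(unique(ds$meta$patient_id),
                            n_outer = 10, n_inner = 10, seed = 7)
    list(ds = ds, plan = plan, cfg = run_config(n_outer = 10, n_inner = 10))
  })
}

# Identity variant tables: every contour variant equals the manual table, the
# limit in which the contour-dependence filter retains everything, so the
# nested-CV run measures pipeline recovery rather than the filter.
identity_variants <- function(tab) {
  list(manual = tab, eroded = tab, dilated = tab, jittered = tab)
}

# Nested-CV run on the recovery cohort with the planted signal.
signal_cv <- function() {
  memo("signal_cv", function() {
    r <- recovery_dataset()
    run_nested_cv(identity_variants(r$ds$variant_tables$manual),
                  r$ds$covariates, r$ds$outcomes, r$ds$meta, r$plan,
                  feature_groups = "radiomic",
                  covariate_groups = r$ds$covariate_groups, config = r$cfg)
  })
}

# Small on-disk cohort shared by the interface tests. A short baseline scale
# raises the event rate so tiny training splits still carry events.
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    cfg <- synthetic_config(
      n_patients = 8,
      lesions_per_patient = list(min = 1, max = 2, probs = c(0.5, 0.5)),
      baseline_hazard = list(shape = 1, scale_months = 20),
      seed = 11)
    dir <- file.path(tempdir(), "tiny_cohort")
    manifest <- generate_cohort(cfg, dir, overwrite = TRUE)
    list(config = cfg, dir = dir, manifest = manifest)
  })
}
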