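#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default: 3 mm margin,
#' 1 mm resampling and erosion/dilation radius, fixed bin width 0.25 (z-score
#' units), significance levels 0.05 (univariate) and 0.10
#' (contour dependence), redundancy threshold |Spearman rho| = 0.8, a 30 x 30
#' nested split plan at 80:20, risk-score trimming at ±2 SD, and at most 4
#' features per Cox model.
#'
#' @param margin_mm peritumoral margin width (> 0).
#' @param perturb_mm contour erosion/dilation radius (>= 0).
#' @param target_mm isotropic resampling voxel length (> 0).
#' @param bin_width histogram/GLCM bin width (> 0).
#' @param alpha_univ univariate Cox significance level in (0, 1].
#' @param alpha_contour contour-dependence significance level in \[0, 1].
#' @param rho_threshold redundancy clustering threshold in (0, 1].
#' @param min_unique,min_cv low-variability filter settings.
#' @param n_outer,n_inner split counts (>= 1).
#' @param train_frac training fraction in (0, 1).
#' @param trim_k ensemble trimming threshold in SD units (> 0).
#' @param max_features maximum Cox model size (1-4 typical).
#' @param feature_groups groups fed to the models.
#' @param seed integer seed for the split plan.
#' @return a validated `run_config` list.
#' @export
run_config <- function(margin_mm = 3.0, perturb_mm = 1.0, target_mm = 1.0,
                       bin_width = 0.25, alpha_univ = 0.05,
                       alpha_contour = 0.10, rho_threshold = 0.8,
                       min_unique = 3, min_cv = 1e-3,
                       n_outer = 30, n_inner = 30, train_frac = 0.8,
                       trim_k = 2.0, max_features = 4,
                       feature_groups = c("radiomic", "clinical"),
                       seed = 1L) {
  stopifnot(margin_mm > 0, perturb_mm >= 0, target_mm > 0, bin_width > 0,
            alpha_univ > 0, alpha_univ <= 1, alpha_contour >= 0,
            alpha_contour <= 1, rho_threshold > 0, rho_threshold <= 1,
            n_outer >= 1, n_inner >= 1, train_frac > 0, train_frac < 1,
            trim_k > 0, max_features >= 1)
  feature_groups <- match.arg(feature_groups,
                              c("radiomic", "clinical", "dosimetric"),
                              several.ok = TRUE)
  structure(list(margin_mm = margin_mm, perturb_mm = perturb_mm,
                 target_mm = target_mm, bin_width = bin_width,
                 alpha_univ = alpha_univ, alpha_contour = alpha_contour,
                 rho_threshold = rho_threshold, min_unique = min_unique,
                 min_cv = min_cv, n_outer = n_outer, n_inner = n_inner,
                 train_frac = train_frac, trim_k = trim_k,
                 max_features = max_features, feature_groups = feature_groups,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a bit-stable JSON report
#'
#' Keys are sorted recursively before writing so identical content always
#' produces identical bytes; numbers are written at full precision.
#'
#' @param report a (nested) list.
#' @param path output path.
#' @return `write_report()` returns `path` invisibly; `load_report()` the
#'   parsed list.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(sort_keys(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
load_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

sort_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, sort_keys)
  } else x
}

#' Load and validate a cohort manifest
#'
#' The manifest lists, per lesion, its ids and the image / GTV / brain-mask
#' (optionally dose) volume paths, plus the clinical and outcome CSV tables.
#' Validation errors are specific: duplicate lesion id, missing file, or a
#' lesion without an outcome row each raise a distinct message.
#'
#' @param path path to `manifest.json`.
#' @return a `cohort_manifest`: list with `lesions` (data.frame), `clinical`,
#'   `outcomes`, `dose` (data.frames), and the source paths.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  les <- do.call(rbind, lapply(m$lesions, function(r) {
    data.frame(lesion_id = r$lesion_id, patient_id = r$patient_id,
               center_id = r$center_id, image = r$image, gtv = r$gtv,
               brain_mask = r$brain_mask,
               dose = if (is.null(r$dose)) NA_character_ else r$dose,
               stringsAsFactors = FALSE)
  }))
  dup <- les$lesion_id[duplicated(les$lesion_id)]
  if (length(dup)) stop("duplicate lesion_id in manifest: ",
                        paste(unique(dup), collapse = ", "))
  for (col in c("image", "gtv", "brain_mask")) {
    missing <- les[[col]][!file.exists(les[[col]])]
    if (length(missing)) stop("manifest references missing file: ", missing[1])
  }
  for (f in c(m$clinical_csv, m$outcomes_csv)) {
    if (!file.exists(f)) stop("manifest references missing file: ", f)
  }
  clinical <- utils::read.csv(m$clinical_csv, stringsAsFactors = FALSE)
  outcomes <- utils::read.csv(m$outcomes_csv, stringsAsFactors = FALSE)
  orphan <- setdiff(les$lesion_id, outcomes$lesion_id)
  if (length(orphan)) stop("lesion without outcome row: ",
                           paste(orphan, collapse = ", "))
  dose <- if (!is.null(m$dose_csv) && file.exists(m$dose_csv)) {
    utils::read.csv(m$dose_csv, stringsAsFactors = FALSE)
  } else NULL
  structure(list(lesions = les, clinical = clinical,
                 outcomes = outcomes[match(les$lesion_id, outcomes$lesion_id), ],
                 dose = dose, path = path,
                 schema_version = m$schema_version %||% "1"),
            class = "cohort_manifest")
}

#' Percentage of failures among a count
#'
#' Cohort summary helper: the percent of events among `n_total`, rounded to
#' one decimal as reported in cohort tables (e.g. lesion-, series- and
#' patient-level local-failure rates).
#'
#' @param n_events,n_total counts.
#' @return percentage rounded to one decimal.
#' @export
event_rate_percent <- function(n_events, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  round(100 * n_events / n_total, 1)
}

#' Preprocess one lesion and extract its per-variant feature rows
#'
#' Resamples image and masks to the target isotropic grid, z-score normalizes
#' within the brain mask, builds the four contour variants and their 3 mm
#' margins, and extracts the radiomic feature row for every variant. The
#' wavelet.LLL channel is computed once and reused across variants.
#'
#' @param image,gtv,brain lesion volumes on a common grid.
#' @param cfg a `run_config`.
#' @param lesion_id id used in error messages and jitter seeding.
#' @param jitter_seed seed of the jittered variant.
#' @return named list of feature rows (`manual`, `eroded`, `dilated`,
#'   `jittered`).
#' @export
lesion_variant_features <- function(image, gtv, brain, cfg = run_config(),
                                    lesion_id = "?", jitter_seed = 1L) {
  if (max(abs(image$spacing_mm - cfg$target_mm)) > 1e-9) {
    image <- resample_isotropic(image, cfg$target_mm, "linear")
    gtv <- resample_isotropic(gtv, cfg$target_mm)
    brain <- resample_isotropic(brain, cfg$target_mm)
  }
  image <- zscore_normalize(image, brain)
  lll <- wavelet_lll(image)
  vars <- contour_variants(gtv, perturb_mm = cfg$perturb_mm,
                           jitter_seed = jitter_seed)
  lapply(vars, function(v) {
    marg <- make_margin(v, cfg$margin_mm, brain)
    extract_lesion_features(image, v, marg, bin_width = cfg$bin_width,
                            lesion_id = lesion_id, lll = lll)
  })
}

#' Build the full modeling dataset of a synthetic cohort in memory
#'
#' Simulates every lesion image of the cohort, runs preprocessing, contour
#' variants and feature extraction, assembles the per-variant radiomic
#' feature tables, the clinical and dosimetric covariates, and the simulated
#' outcomes. GLCM Correlation columns that are undefined for any lesion are
#' dropped with a warning. This is the disk-free twin of
#' [extract_manifest_features()] used for simulation studies.
#'
#' @param config a `synthetic_config`.
#' @param cfg a `run_config`.
#' @param seed cohort seed (defaults to `config$seed`).
#' @return list `variant_tables`, `covariates`, `covariate_groups`,
#'   `outcomes`, `meta`, `cohort`.
#' @export
build_feature_dataset <- function(config, cfg = run_config(),
                                  seed = config$seed) {
  cohort <- sample_cohort(config, seed = seed)
  outcomes <- simulate_outcomes(cohort$lesions, config,
                                seed = derive_seed(seed, 0))
  n <- nrow(cohort$lesions)
  rows <- vector("list", n)
  dvh <- vector("list", n)
  for (i in seq_len(n)) {
    les <- cohort$lesions[i, ]
    sim <- simulate_lesion_image(les, config)
    rows[[i]] <- lesion_variant_features(sim$image, sim$gtv, sim$brain, cfg,
                                         lesion_id = les$lesion_id,
                                         jitter_seed = derive_seed(les$image_seed, 1))
    dvh[[i]] <- dvh_metrics(simulate_dose_grid(sim$gtv, les$total_dose_gy),
                            sim$gtv)
  }
  variant_tables <- assemble_variant_tables(rows, cohort$lesions$lesion_id)
  clinical <- cohort$lesions[, c("kps_high", "systemic_before",
                                 "systemic_during", "systemic_after",
                                 "age", "n_lesions")]
  dosim <- as.data.frame(do.call(rbind, dvh))
  dosim$BED10 <- compute_bed(cohort$lesions$total_dose_gy,
                             cohort$lesions$n_fractions, 10)
  covariates <- cbind(clinical, dosim)
  rownames(covariates) <- cohort$lesions$lesion_id
  covariate_groups <- stats::setNames(
    c(rep("clinical", ncol(clinical)), rep("dosimetric", ncol(dosim))),
    colnames(covariates))
  meta <- data.frame(lesion_id = cohort$lesions$lesion_id,
                     patient_id = cohort$lesions$patient_id,
                     center_id = cohort$lesions$center_id,
                     stringsAsFactors = FALSE)
  list(variant_tables = variant_tables, covariates = covariates,
       covariate_groups = covariate_groups,
       outcomes = outcomes[, c("lesion_id", "time_months", "event")],
       meta = meta, cohort = cohort)
}

#' Stack per-lesion variant rows into aligned per-variant tables
#' @noRd
assemble_variant_tables <- function(rows, lesion_ids) {
  variants <- names(rows[[1]])
  tables <- lapply(variants, function(v) {
    tb <- as.data.frame(do.call(rbind, lapply(rows, `[[`, v)))
    rownames(tb) <- lesion_ids
    tb
  })
  names(tables) <- variants
  # drop columns undefined for any lesion in any variant (e.g. GLCM
  # Correlation of a single-gray-level region)
  bad <- Reduce(`|`, lapply(tables, function(tb) vapply(tb, anyNA, logical(1))))
  if (any(bad)) {
    warning("dropping ", sum(bad), " feature(s) undefined for some lesion: ",
            paste(utils::head(colnames(tables[[1]])[bad], 5), collapse = ", "),
            call. = FALSE)
    tables <- lapply(tables, function(tb) tb[, !bad, drop = FALSE])
  }
  tables
}

#' Extract the modeling dataset from an on-disk cohort manifest
#'
#' Disk-based twin of [build_feature_dataset()]: reads each lesion's volumes,
#' preprocesses, extracts the per-variant radiomic rows, computes DVH metrics
#' from the dose grid when present and BED from the dose table, and joins the
#' clinical covariates.
#'
#' @param manifest a `cohort_manifest` from [load_manifest()].
#' @param cfg a `run_config`.
#' @return same structure as [build_feature_dataset()] (without `cohort`).
#' @export
extract_manifest_features <- function(manifest, cfg = run_config()) {
  les <- manifest$lesions
  n <- nrow(les)
  rows <- vector("list", n)
  dvh <- vector("list", n)
  for (i in seq_len(n)) {
    image <- read_volume(les$image[i])
    gtv <- read_volume(les$gtv[i], mask = TRUE)
    brain <- read_volume(les$brain_mask[i], mask = TRUE)
    rows[[i]] <- lesion_variant_features(image, gtv, brain, cfg,
                                         lesion_id = les$lesion_id[i],
                                         jitter_seed = derive_seed(cfg$seed, i))
    if (!is.na(les$dose[i])) {
      dose <- read_volume(les$dose[i])
      if (max(abs(dose$spacing_mm - cfg$target_mm)) > 1e-9) {
        dose <- resample_isotropic(dose, cfg$target_mm, "linear")
        gtv_r <- resample_isotropic(gtv, cfg$target_mm)
      } else gtv_r <- gtv
      dvh[[i]] <- dvh_metrics(dose, gtv_r)
    }
  }
  variant_tables <- assemble_variant_tables(rows, les$lesion_id)
  cl <- manifest$clinical
  pat_i <- match(les$patient_id, cl$patient_id)
  clinical <- data.frame(kps_high = cl$kps_high[pat_i],
                         systemic_before = cl$systemic_before[pat_i],
                         systemic_during = cl$systemic_during[pat_i],
                         systemic_after = cl$systemic_after[pat_i],
                         age = cl$age[pat_i],
                         n_lesions = cl$n_lesions[pat_i])
  covariates <- clinical
  groups <- rep("clinical", ncol(clinical))
  if (!is.null(dvh[[1]])) {
    dosim <- as.data.frame(do.call(rbind, dvh))
    if (!is.null(manifest$dose)) {
      d_i <- match(les$lesion_id, manifest$dose$lesion_id)
      dosim$BED10 <- compute_bed(manifest$dose$total_dose_gy[d_i],
                                 manifest$dose$n_fractions[d_i], 10)
    }
    covariates <- cbind(clinical, dosim)
    groups <- c(groups, rep("dosimetric", ncol(dosim)))
  }
  rownames(covariates) <- les$lesion_id
  covariate_groups <- stats::setNames(groups, colnames(covariates))
  outcomes <- manifest$outcomes[, c("lesion_id", "time_months", "event")]
  meta <- data.frame(lesion_id = les$lesion_id, patient_id = les$patient_id,
                     center_id = les$center_id, stringsAsFactors = FALSE)
  list(variant_tables = variant_tables, covariates = covariates,
       covariate_groups = covariate_groups, outcomes = outcomes, meta = meta)
}

#' Serialize trained ensembles to a bit-stable JSON file
#'
#' @param ensembles list of `ensemble_model` (NULLs allowed).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_ensembles <- function(ensembles, path) {
  ser <- lapply(ensembles, function(e) {
    if (is.null(e)) return(NULL)
    list(outer_split = e$outer_split, trim_k = e$trim_k,
         members = lapply(e$members, function(m) {
           list(features = as.list(m$features), coef = as.list(m$coef),
                center = as.list(m$center), scale = as.list(m$scale),
                split_id = m$split_id)
         }))
  })
  write_report(list(ensembles = ser), path)
}

#' Run the full pipeline on a manifest with stage-level caching
#'
#' Executes extraction (preprocessing + contours + features) and nested-CV
#' training, writing per-variant feature CSVs, the covariate CSV, the trained
#' ensembles and the evaluation report into `run_dir`. Each stage records the
#' MD5 hashes of its inputs; on a rerun a stage is skipped when its outputs
#' exist and the recorded input hashes are unchanged, so corrupting an
#' intermediate file reruns only the stages downstream of it.
#'
#' @param manifest a `cohort_manifest`.
#' @param cfg a `run_config`.
#' @param run_dir output directory.
#' @return list with `report` and the paths of the written artifacts; the
#'   element `stages_run` names the stages actually executed.
#' @export
run_all <- function(manifest, cfg = run_config(), run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(run_dir, "stage_state.json")
  state <- if (file.exists(state_path)) load_report(state_path) else list()
  cfg_hash <- digest_of(vapply(cfg, paste, character(1), collapse = ","))
  stages_run <- character(0)

  variant_names <- c("manual", "eroded", "dilated", "jittered")
  feat_paths <- file.path(run_dir, paste0("features_", variant_names, ".csv"))
  cov_path <- file.path(run_dir, "covariates.csv")
  meta_path <- file.path(run_dir, "meta.csv")

  extract_inputs <- c(manifest$path, manifest$lesions$image,
                      manifest$lesions$gtv, manifest$lesions$brain_mask)
  extract_sig <- c(unname(tools::md5sum(extract_inputs)), cfg_hash)
  extract_outputs <- c(feat_paths, cov_path, meta_path)
  if (!stage_fresh(state$extract, extract_sig, extract_outputs)) {
    ds <- extract_manifest_features(manifest, cfg)
    for (k in seq_along(variant_names)) {
      utils::write.csv(ds$variant_tables[[variant_names[k]]], feat_paths[k])
    }
    utils::write.csv(ds$covariates, cov_path)
    utils::write.csv(ds$meta, meta_path, row.names = FALSE)
    write_report(as.list(ds$covariate_groups),
                 file.path(run_dir, "covariate_groups.json"))
    state$extract <- list(sig = extract_sig)
    stages_run <- c(stages_run, "extract")
    write_report(state, state_path)
  }

  report_path <- file.path(run_dir, "report.json")
  ensembles_path <- file.path(run_dir, "ensembles.json")
  train_inputs <- c(extract_outputs, manifest$path)
  train_sig <- c(unname(tools::md5sum(train_inputs)), cfg_hash)
  if (!stage_fresh(state$train, train_sig, c(report_path, ensembles_path))) {
    variant_tables <- lapply(feat_paths, function(p)
      utils::read.csv(p, row.names = 1, check.names = FALSE))
    names(variant_tables) <- variant_names
    covariates <- utils::read.csv(cov_path, row.names = 1, check.names = FALSE)
    covariate_groups <- unlist(load_report(
      file.path(run_dir, "covariate_groups.json")))
    meta <- manifest$lesions[, c("lesion_id", "patient_id")]
    plan <- make_split_plan(unique(meta$patient_id), n_outer = cfg$n_outer,
                            n_inner = cfg$n_inner,
                            train_frac = cfg$train_frac, seed = cfg$seed)
    res <- run_nested_cv(variant_tables, covariates, manifest$outcomes, meta,
                         plan, feature_groups = cfg$feature_groups,
                         covariate_groups = covariate_groups, config = cfg)
    write_report(res$report, report_path)
    write_ensembles(res$ensembles, ensembles_path)
    state$train <- list(sig = train_sig)
    stages_run <- c(stages_run, "train")
    write_report(state, state_path)
  }

  list(report = load_report(report_path), report_path = report_path,
       ensembles_path = ensembles_path, feature_paths = feat_paths,
       stages_run = stages_run)
}

stage_fresh <- function(st, sig, outputs) {
  !is.null(st) && identical(unname(unlist(st$sig)), unname(sig)) &&
    all(file.exists(outputs))
}

#' MD5 of a character vector (stable content hash for configs)
#' @noRd
digest_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(x, collapse = "\n"), f)
  unname(tools::md5sum(f))
}
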