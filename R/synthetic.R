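#' Configuration of the synthetic multicenter cohort
#'
#' Defines the study conditions emulated by the generator: multi-lesion
#' patients nested in centers, ellipsoidal enhancing lesions whose 3 mm
#' peritumoral intensity profile carries the outcome signal (the latent
#' `infiltration` drives both the rim amplitude and the hazard), clinical
#' covariates (KPS band, systemic-therapy flags, age, lesion count) with a
#' center-specific KPS mix, per-lesion dose prescriptions (single-fraction
#' radiosurgery or fractionated regimens), and right-censored local-failure
#' times drawn from a Weibull-baseline Cox model with known coefficients.
#'
#' @param n_patients number of patients (>= 1).
#' @param lesions_per_patient list `min`, `max`, `probs` (probabilities of
#'   `min:max` lesions; must sum to 1).
#' @param n_centers number of centers.
#' @param center_effects list (length `n_centers`) of per-center lists with
#'   `intensity_scale`, `spacing_mm`, `kps_probs` (probabilities of KPS bands
#'   60 / 70-80 / 90-100), and `assign_prob` (patient allocation weight).
#' @param true_betas named numeric log-hazard coefficients; names must
#'   resolve to lesion-level latents or covariates (`infiltration`,
#'   `kps_high`, `systemic_before`, `systemic_during`, `systemic_after`,
#'   `age`, `n_lesions`).
#' @param baseline_hazard list `shape`, `scale_months` of the Weibull
#'   baseline (shape 1 = exponential).
#' @param censor_time list `admin_months` (administrative follow-up) and
#'   `dropout_range` (uniform dropout window, months).
#' @param image_geometry list `dim` (grid size), `spacing_mm`,
#'   `radius_range_mm` (lesion radius range).
#' @param intensity list `background`, `core`, `rim_tau_mm` (rim decay
#'   length), `texture_sd` (in-lesion texture).
#' @param noise_sd white-noise SD in intensity units.
#' @param seed integer base seed; every artifact is a pure function of
#'   (config, seed).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_patients = 40,
    lesions_per_patient = list(min = 1, max = 5,
                               probs = c(0.35, 0.25, 0.18, 0.12, 0.10)),
    n_centers = 3,
    center_effects = NULL,
    true_betas = c(infiltration = 1.5, kps_high = -0.7, systemic_before = -0.5),
    baseline_hazard = list(shape = 1, scale_months = 90),
    censor_time = list(admin_months = 24, dropout_range = c(6, 24)),
    image_geometry = list(dim = c(32L, 32L, 32L), spacing_mm = c(1, 1, 1),
                          radius_range_mm = c(3, 7)),
    intensity = list(background = 100, core = 180, rim_tau_mm = 1.5,
                     texture_sd = 4),
    noise_sd = 20,
    seed = 1L) {
  if (is.null(center_effects)) {
    center_effects <- list(
      list(intensity_scale = 1, spacing_mm = image_geometry$spacing_mm,
           kps_probs = c(0.05, 0.20, 0.75), assign_prob = 0.45),
      list(intensity_scale = 1, spacing_mm = image_geometry$spacing_mm,
           kps_probs = c(0.05, 0.18, 0.77), assign_prob = 0.40),
      list(intensity_scale = 1, spacing_mm = image_geometry$spacing_mm,
           kps_probs = c(0.15, 0.45, 0.40), assign_prob = 0.15)
    )[seq_len(n_centers)]
  }
  stopifnot(n_patients >= 1, n_centers >= 1,
            length(center_effects) == n_centers)
  lp <- lesions_per_patient
  n_levels <- lp$max - lp$min + 1L
  if (is.null(lp$probs)) lp$probs <- rep(1 / n_levels, n_levels)
  if (length(lp$probs) != n_levels || abs(sum(lp$probs) - 1) > 1e-8) {
    stop("lesions_per_patient$probs must have length max-min+1 and sum to 1")
  }
  for (ce in center_effects) {
    if (abs(sum(ce$kps_probs) - 1) > 1e-8) stop("kps_probs must sum to 1")
  }
  if (image_geometry$radius_range_mm[1] <= 0) stop("lesion radii must be > 0")
  if (censor_time$admin_months <= 0) stop("censor_time must be > 0")
  if (baseline_hazard$shape <= 0 || baseline_hazard$scale_months <= 0) {
    stop("baseline hazard shape and scale must be > 0")
  }
  structure(list(
    n_patients = as.integer(n_patients), lesions_per_patient = lp,
    n_centers = as.integer(n_centers), center_effects = center_effects,
    true_betas = true_betas, baseline_hazard = baseline_hazard,
    censor_time = censor_time, image_geometry = image_geometry,
    intensity = intensity, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

kps_bands <- c("60", "70-80", "90-100")

#' Sample the latent cohort (patients, covariates, lesion latents)
#'
#' Deterministic for a fixed (config, seed). Patient-level covariates are
#' sampled independently except the KPS band, whose mix is center-specific.
#' Each lesion gets an id, an ellipsoid (center, semi-axes, orientation), and
#' a latent `infiltration` in \[0, 1\] that scales the peritumoral rim.
#'
#' @param config a `synthetic_config`.
#' @param seed overrides `config$seed` when given.
#' @return list with data.frames `patients` and `lesions`.
#' @export
sample_cohort <- function(config, seed = config$seed) {
  geom <- config$image_geometry
  with_seed(seed, {
    np <- config$n_patients
    assign_w <- vapply(config$center_effects, function(ce)
      ce$assign_prob %||% 1, numeric(1))
    center <- sample.int(config$n_centers, np, replace = TRUE,
                         prob = assign_w / sum(assign_w))
    kps_band <- vapply(center, function(cc)
      sample(kps_bands, 1, prob = config$center_effects[[cc]]$kps_probs),
      character(1))
    lp <- config$lesions_per_patient
    n_lesions <- sample(seq(lp$min, lp$max), np, replace = TRUE, prob = lp$probs)
    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(np)),
      center_id = center,
      age = round(stats::rnorm(np, 62, 14), 1),
      kps_band = kps_band,
      kps_high = as.integer(kps_band == "90-100"),
      systemic_before = stats::rbinom(np, 1, 0.65),
      systemic_during = stats::rbinom(np, 1, 0.63),
      systemic_after = stats::rbinom(np, 1, 0.76),
      n_lesions = n_lesions,
      stringsAsFactors = FALSE
    )
    total <- sum(n_lesions)
    pat_of <- rep(seq_len(np), n_lesions)
    extent <- geom$dim * geom$spacing_mm
    rr <- geom$radius_range_mm
    lesions <- data.frame(
      lesion_id = sprintf("L%04d", seq_len(total)),
      patient_id = patients$patient_id[pat_of],
      center_id = patients$center_id[pat_of],
      stringsAsFactors = FALSE
    )
    radius <- stats::runif(total, rr[1], rr[2])
    aniso <- matrix(stats::runif(total * 3, 0.85, 1.15), total, 3)
    semi <- radius * aniso
    lesions$semi_a <- semi[, 1]; lesions$semi_b <- semi[, 2]; lesions$semi_c <- semi[, 3]
    jitter <- matrix(stats::runif(total * 3, -1, 1), total, 3)
    lesions$cx <- extent[1] / 2 + jitter[, 1]
    lesions$cy <- extent[2] / 2 + jitter[, 2]
    lesions$cz <- extent[3] / 2 + jitter[, 3]
    ang <- matrix(stats::runif(total * 3, 0, pi), total, 3)
    lesions$rot_a <- ang[, 1]; lesions$rot_b <- ang[, 2]; lesions$rot_g <- ang[, 3]
    lesions$infiltration <- stats::runif(total)
    lesions$texture_sd <- config$intensity$texture_sd
    # merge patient covariates onto lesions
    for (col in c("age", "kps_band", "kps_high", "systemic_before",
                  "systemic_during", "systemic_after", "n_lesions")) {
      lesions[[col]] <- patients[[col]][pat_of]
    }
    # per-lesion image seeds are substreams of the cohort seed, so adding a
    # lesion does not perturb the images of the others
    lesions$image_seed <- derive_seed(seed, seq_len(total))
    # dose prescription: mostly single-fraction radiosurgery
    srs <- stats::runif(total) < 0.67
    lesions$total_dose_gy <- ifelse(srs, sample(c(18, 20), total, TRUE, c(0.3, 0.7)), 51)
    lesions$n_fractions <- ifelse(srs, 1L, 12L)
    list(patients = patients, lesions = lesions)
  })
}

rotation_matrix <- function(a, b, g) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Simulate one lesion image with a peritumoral rim
#'
#' Rasterizes the latent ellipsoid on the grid and builds the image as
#' background + core plateau inside the mask + an exponentially decaying rim
#' outside it, `infiltration * (core - background) * exp(-d / tau)` where `d`
#' is the exact Euclidean distance to the mask, plus white noise and
#' in-lesion texture. The rim places the outcome signal exactly where the
#' peritumoral-margin features look for it. Deterministic for a fixed seed.
#'
#' @param latent one-row data.frame (a row of `sample_cohort()$lesions`) or
#'   an equivalent named list.
#' @param config a `synthetic_config` (geometry, intensity model, noise).
#' @param seed RNG seed for the noise; defaults to the lesion's `image_seed`.
#' @return list with `image` (`voxel_volume`), `gtv` and `brain`
#'   (`binary_mask`).
#' @export
simulate_lesion_image <- function(latent, config, seed = latent$image_seed) {
  geom <- config$image_geometry
  ints <- config$intensity
  ce <- config$center_effects[[latent$center_id]]
  spacing <- ce$spacing_mm %||% geom$spacing_mm
  d <- as.integer(geom$dim)
  extent <- d * spacing
  semi <- c(latent$semi_a, latent$semi_b, latent$semi_c)
  ctr <- c(latent$cx, latent$cy, latent$cz)
  margin_need <- max(semi) + 3 + max(spacing)
  if (any(ctr - margin_need < 0) || any(ctr + margin_need > extent)) {
    stop(sprintf("lesion %s exceeds the image grid (needs %.1f mm clearance)",
                 latent$lesion_id %||% "?", margin_need))
  }
  # voxel centers
  xs <- (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spacing[2]
  zs <- (seq_len(d[3]) - 0.5) * spacing[3]
  X <- cbind(rep(xs, times = d[2] * d[3]),
             rep(rep(ys, each = d[1]), times = d[3]),
             rep(zs, each = d[1] * d[2]))
  R <- rotation_matrix(latent$rot_a, latent$rot_b, latent$rot_g)
  Q <- sweep((sweep(X, 2, ctr) %*% R), 2, semi, `/`)
  inside <- rowSums(Q^2) <= 1
  mask <- array(inside + 0L, dim = d)
  if (!any(inside)) stop(sprintf("lesion %s rasterizes to an empty mask",
                                 latent$lesion_id %||% "?"))
  dist_out <- sqrt(edt_squared(mask != 0, spacing))
  contrast <- ints$core - ints$background
  infil <- latent$infiltration
  img <- ints$background + contrast * (mask != 0) +
    infil * contrast * exp(-dist_out / ints$rim_tau_mm) * (mask == 0)
  scale <- ce$intensity_scale %||% 1
  img <- img * scale
  if (config$noise_sd > 0 || (latent$texture_sd %||% 0) > 0) {
    img <- img + with_seed(seed, {
      noise <- stats::rnorm(length(img), 0, config$noise_sd)
      tex <- stats::rnorm(length(img), 0, latent$texture_sd %||% 0)
      noise + tex * as.numeric(mask != 0)
    })
  }
  # brain mask: ellipsoid filling the grid minus a 1 mm shell
  B <- sweep(sweep(X, 2, extent / 2), 2, extent / 2 - 1, `/`)
  brain <- array((rowSums(B^2) <= 1) + 0L, dim = d)
  list(image = voxel_volume(array(img, dim = d), spacing),
       gtv = binary_mask(mask, spacing),
       brain = binary_mask(brain, spacing))
}

#' Simulate right-censored local-failure outcomes
#'
#' Event times follow a Weibull-baseline proportional hazards model,
#' `h(t) = h0(t) exp(sum(beta * x))`, sampled in closed form; observation
#' stops at the administrative follow-up or a uniform dropout time, whichever
#' comes first.
#'
#' @param lesions data.frame with one row per lesion containing every column
#'   named in `true_betas`.
#' @param config a `synthetic_config` (betas, baseline hazard, censoring).
#' @param seed RNG seed.
#' @return data.frame `lesion_id`, `time_months` (> 0), `event` (0/1), and
#'   the true linear predictor `lp_true`.
#' @export
simulate_outcomes <- function(lesions, config, seed = config$seed) {
  betas <- config$true_betas
  missing <- setdiff(names(betas), colnames(lesions))
  if (length(missing)) {
    stop("true_betas name(s) not found among latents/covariates: ",
         paste(missing, collapse = ", "))
  }
  Xb <- as.matrix(lesions[, names(betas), drop = FALSE])
  lp <- drop(Xb %*% betas)
  shape <- config$baseline_hazard$shape
  scale <- config$baseline_hazard$scale_months
  admin <- config$censor_time$admin_months
  dr <- config$censor_time$dropout_range
  n <- nrow(lesions)
  with_seed(seed, {
    u <- stats::runif(n)
    t_event <- scale * (-log(u) / exp(lp))^(1 / shape)
    dropout <- stats::runif(n, dr[1], dr[2])
    censor <- pmin(admin, dropout)
    time <- pmax(pmin(t_event, censor), 1e-6)
    data.frame(lesion_id = lesions$lesion_id %||% seq_len(n),
               time_months = time,
               event = as.integer(t_event <= censor),
               lp_true = lp,
               stringsAsFactors = FALSE)
  })
}

#' Generate a cohort on disk (images, masks, dose, tables, manifest)
#'
#' Writes per-lesion NIfTI volumes (image, GTV mask, brain mask, dose grid),
#' the clinical, dose and outcome CSV tables, a JSON manifest listing all
#' paths, and a ground-truth sidecar with the latent parameters. Refuses to
#' overwrite an existing manifest unless `overwrite = TRUE`.
#'
#' @param config a `synthetic_config`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed`.
#' @param overwrite allow replacing an existing manifest.
#' @param write_dose also write per-lesion dose grids.
#' @return the manifest (invisibly), as returned by [load_manifest()].
#' @export
generate_cohort <- function(config, out_dir, seed = config$seed,
                            overwrite = FALSE, write_dose = TRUE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists (use overwrite = TRUE): ", manifest_path)
  }
  dir.create(file.path(out_dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  coh <- sample_cohort(config, seed = seed)
  outcomes <- simulate_outcomes(coh$lesions, config, seed = derive_seed(seed, 0))

  records <- vector("list", nrow(coh$lesions))
  for (i in seq_len(nrow(coh$lesions))) {
    les <- coh$lesions[i, ]
    sim <- simulate_lesion_image(les, config)
    img_p <- file.path(out_dir, "volumes", paste0("image_", les$lesion_id, ".nii.gz"))
    gtv_p <- file.path(out_dir, "volumes", paste0("gtv_", les$lesion_id, ".nii.gz"))
    brn_p <- file.path(out_dir, "volumes", paste0("brain_", les$lesion_id, ".nii.gz"))
    write_volume(sim$image, img_p)
    write_volume(sim$gtv, gtv_p)
    write_volume(sim$brain, brn_p)
    dose_p <- NULL
    if (write_dose) {
      dose_p <- file.path(out_dir, "volumes", paste0("dose_", les$lesion_id, ".nii.gz"))
      write_volume(simulate_dose_grid(sim$gtv, les$total_dose_gy), dose_p)
    }
    records[[i]] <- list(lesion_id = les$lesion_id, patient_id = les$patient_id,
                         center_id = les$center_id, image = img_p, gtv = gtv_p,
                         brain_mask = brn_p, dose = dose_p)
  }
  clinical_csv <- file.path(out_dir, "clinical.csv")
  outcomes_csv <- file.path(out_dir, "outcomes.csv")
  dose_csv <- file.path(out_dir, "dose.csv")
  utils::write.csv(coh$patients, clinical_csv, row.names = FALSE)
  utils::write.csv(outcomes[, c("lesion_id", "time_months", "event")],
                   outcomes_csv, row.names = FALSE)
  utils::write.csv(coh$lesions[, c("lesion_id", "total_dose_gy", "n_fractions")],
                   dose_csv, row.names = FALSE)
  sidecar <- file.path(out_dir, "ground_truth.json")
  write_report(list(lesions = coh$lesions, true_betas = as.list(config$true_betas),
                    lp_true = stats::setNames(as.list(outcomes$lp_true),
                                              outcomes$lesion_id)),
               sidecar)
  manifest <- list(schema_version = "1",
                   lesions = records,
                   clinical_csv = clinical_csv,
                   outcomes_csv = outcomes_csv,
                   dose_csv = dose_csv,
                   ground_truth = sidecar,
                   seed = as.integer(seed))
  write_report(manifest, manifest_path)
  invisible(load_manifest(manifest_path))
}

#' Simple dose grid: prescription inside the GTV, exponential falloff outside
#' @noRd
simulate_dose_grid <- function(gtv, prescription_gy, falloff_mm = 4) {
  d <- sqrt(edt_squared(gtv$values != 0, gtv$spacing_mm))
  voxel_volume(prescription_gy * exp(-d / falloff_mm),
               gtv$spacing_mm, gtv$origin_mm)
}
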