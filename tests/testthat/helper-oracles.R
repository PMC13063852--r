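# Independent oracle implementations used to cross-check the package's
# statistical kernel. These deliberately share no code with the package.

# O(n^2) triple-condition pair enumeration of Harrell's c-index.
brute_force_cindex <- function(scores, time, event) {
  n <- length(scores)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # pair (i earlier) comparable iff subject i has an event and either
      # t_i < t_j, or t_i == t_j with j censored
      comparable <- event[i] == 1 &&
        (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
      if (!comparable) next
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Exact Cox partial log-likelihood for a single covariate with distinct event
# times (no ties, so Breslow/Efron/exact coincide).
cox_pl_1d <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-stage grid maximization of the exact 1-D partial likelihood.
grid_max_cox <- function(x, time, event, lo = -5, hi = 5) {
  g1 <- seq(lo, hi, by = 1e-3)
  b1 <- g1[which.max(vapply(g1, cox_pl_1d, numeric(1), x, time, event))]
  g2 <- seq(b1 - 2e-3, b1 + 2e-3, by = 1e-6)
  g2[which.max(vapply(g2, cox_pl_1d, numeric(1), x, time, event))]
}

# Random survival cohort with heavy ties in times and scores, for exact
# equality checks of the c-index against the brute-force oracle.
random_tied_cohort <- function(n) {
  list(scores = sample(1:5, n, replace = TRUE) + 0,
       time = sample(1:8, n, replace = TRUE) + 0,
       event = rbinom(n, 1, 0.6))
}

# Digital ball mask on a cubic grid (voxel centers at (i-0.5)*spacing).
ball_mask <- function(radius_mm, dim = rep(2 * ceiling(radius_mm) + 9, 3),
                      spacing = c(1, 1, 1)) {
  ctr <- dim * spacing / 2
  xs <- (seq_len(dim[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dim[2]) - 0.5) * spacing[2]
  zs <- (seq_len(dim[3]) - 0.5) * spacing[3]
  D2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`), (zs - ctr[3])^2, `+`)
  binary_mask((D2 <= radius_mm^2) + 0L, spacing)
}

# Brute-force morphology with a physical ball, voxel-center metric.
brute_ball_morph <- function(mask, mode, radius_mm) {
  m <- mask$values != 0
  d <- dim(m)
  sp <- mask$spacing_mm
  idx <- arrayInd(seq_along(m), d)
  pts <- sweep(idx, 2, sp, `*`)
  src <- if (mode == "dilate") which(m) else which(!m)
  out <- logical(length(m))
  r2 <- radius_mm^2 + 1e-9
  for (v in seq_along(m)) {
    d2 <- (pts[src, 1] - pts[v, 1])^2 + (pts[src, 2] - pts[v, 2])^2 +
      (pts[src, 3] - pts[v, 3])^2
    near <- any(d2 <= r2)
    out[v] <- if (mode == "dilate") near else (m[v] && !near)
  }
  array(out + 0L, d)
}

# One-row lesion latent table accepted by simulate_lesion_image().
toy_latent <- function(infiltration, config, semi = c(4, 4, 4),
                       lesion_id = "L0001") {
  extent <- config$image_geometry$dim * config$image_geometry$spacing_mm
  data.frame(lesion_id = lesion_id, patient_id = "P001", center_id = 1L,
             semi_a = semi[1], semi_b = semi[2], semi_c = semi[3],
             cx = extent[1] / 2, cy = extent[2] / 2, cz = extent[3] / 2,
             rot_a = 0, rot_b = 0, rot_g = 0,
             infiltration = infiltration,
             texture_sd = config$intensity$texture_sd,
             image_seed = 42L, stringsAsFactors = FALSE)
}
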