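#' Canonical radiomic feature names
#'
#' Features are addressed as `"Region_filter_family_name"`, e.g.
#' `"Margin_wavelet.LLL_firstorder_90Percentile"`: the region is the GTV or
#' the 3 mm peritumoral margin, the filter is the original image or its
#' wavelet low-pass (LLL) channel, and the family is `firstorder`, `shape`,
#' or `glcm`.
#'
#' @param region `"GTV"` or `"Margin"`.
#' @param filter `"original"` or `"wavelet.LLL"`.
#' @param family `"firstorder"`, `"shape"`, or `"glcm"`.
#' @param name feature name within the family.
#' @return `feature_name()` returns the canonical string;
#'   `parse_feature_name()` returns a list with the four fields, or `NULL`
#'   when the string is not a canonical radiomic name (e.g. a clinical
#'   covariate).
#' @export
feature_name <- function(region, filter, family, name) {
  region <- match.arg(region, c("GTV", "Margin"))
  filter <- match.arg(filter, c("original", "wavelet.LLL"))
  family <- match.arg(family, c("firstorder", "shape", "glcm"))
  paste(region, filter, family, name, sep = "_")
}

#' @rdname feature_name
#' @param x a character string.
#' @export
parse_feature_name <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)[[1]]
  if (length(parts) < 4L) return(NULL)
  region <- parts[1]; filter <- parts[2]; family <- parts[3]
  name <- paste(parts[-(1:3)], collapse = "_")
  if (!region %in% c("GTV", "Margin")) return(NULL)
  if (!filter %in% c("original", "wavelet.LLL")) return(NULL)
  if (!family %in% c("firstorder", "shape", "glcm")) return(NULL)
  list(region = region, filter = filter, family = family, name = name)
}

is_radiomic_name <- function(x) {
  vapply(x, function(s) !is.null(parse_feature_name(s)), logical(1))
}

# Coiflet-1 analysis low-pass taps, DC gain normalized to 1. The dominant tap
# defines the filter origin (offsets -3..2 around each voxel).
coif1_lowpass <- local({
  h <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
         0.852572020212255, 0.337897662457809, -0.072732619512854)
  h / sum(h)
})

#' Undecimated 3-D wavelet low-pass (LLL channel)
#'
#' Applies a single-level separable analysis low-pass along each axis without
#' downsampling, producing the `wavelet.LLL` image channel on the same grid.
#' The default filter is the 6-tap Coiflet-1 scaling filter with its DC gain
#' normalized to 1 (a constant volume passes through unchanged). Boundaries
#' use whole-sample symmetric reflection.
#'
#' @param volume a `voxel_volume`.
#' @param taps numeric low-pass filter taps; normalized to sum 1 internally.
#' @return the filtered `voxel_volume`.
#' @export
wavelet_lll <- function(volume, taps = coif1_lowpass) {
  h <- taps / sum(taps)
  origin <- which.max(abs(h))
  offsets <- seq_along(h) - origin
  x <- volume$values
  d <- dim(x)
  for (ax in 1:3) {
    n <- d[ax]
    perm <- c(ax, setdiff(1:3, ax))
    M <- aperm(x, perm)
    dim(M) <- c(n, length(M) / n)
    out <- matrix(0, n, ncol(M))
    for (k in seq_along(h)) {
      idx <- reflect_index(seq_len(n) + offsets[k], n)
      out <- out + h[k] * M[idx, , drop = FALSE]
    }
    dim(out) <- d[perm]
    x <- aperm(out, order(perm))
  }
  voxel_volume(x, volume$spacing_mm, volume$origin_mm)
}

#' Reflect out-of-range indices (whole-sample symmetry about the edges)
#' @noRd
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx >= n, period - idx, idx)
  as.integer(idx + 1L)
}

first_order_names <- c("Mean", "Median", "10Percentile", "90Percentile",
                       "Minimum", "Maximum", "Energy", "Entropy", "Skewness",
                       "Kurtosis", "Variance", "InterquartileRange")

#' First-order intensity statistics
#'
#' Twelve intensity statistics of the voxel values inside a region.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Entropy is computed on a fixed-bin-width
#' histogram (`bin_width`, default 0.25 in z-score units, edges anchored at
#' the minimum); Variance, Skewness and Kurtosis use population moments
#' (Kurtosis is not excess-corrected). Skewness and Kurtosis of a constant
#' region are defined as 0.
#'
#' @param values numeric vector of region intensities (length >= 2).
#' @param bin_width histogram bin width for Entropy.
#' @return named numeric vector of the 12 statistics.
#' @export
first_order <- function(values, bin_width = 0.25) {
  if (length(values) < 2L) stop("first_order needs at least 2 values")
  n <- length(values)
  m <- mean(values)
  v <- mean((values - m)^2)
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  p <- hist_probs(values, bin_width)
  entropy <- -sum(p * log2(p))
  skew <- if (v > 0) mean((values - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((values - m)^4) / v^2 else 0
  c(Mean = m, Median = q[3], `10Percentile` = q[1], `90Percentile` = q[5],
    Minimum = min(values), Maximum = max(values), Energy = sum(values^2),
    Entropy = entropy, Skewness = skew, Kurtosis = kurt, Variance = v,
    InterquartileRange = q[4] - q[2])
}

#' Fixed-bin-width histogram probabilities (nonzero bins only)
#' @noRd
hist_probs <- function(values, bin_width) {
  g <- discretize_fixed_width(values, bin_width)
  p <- tabulate(g) / length(g)
  p[p > 0]
}

#' Discretize values with fixed bin width, edges anchored at the minimum
#' @noRd
discretize_fixed_width <- function(values, bin_width) {
  g <- floor((values - min(values)) / bin_width) + 1L
  as.integer(g)
}

#' Shape features of a binary mask
#'
#' Mesh-free shape descriptors in physical units: `VoxelVolume_mm3` (voxel
#' count times voxel volume), `SurfaceArea_mm2` by the co-area estimator
#' (the indicator is smoothed with a separable 1/4-1/2-1/4 kernel and the
#' central-difference gradient magnitude is integrated over the grid),
#' `Sphericity` = pi^(1/3) (6V)^(2/3) / A, and `Maximum3DDiameter`, the
#' largest center-to-center distance between boundary voxels.
#'
#' @param mask nonempty `binary_mask`.
#' @return named numeric vector of the 4 descriptors.
#' @export
shape_features <- function(mask) {
  if (mask_count(mask) == 0L) stop("shape_features: empty mask")
  sp <- mask$spacing_mm
  vol <- mask_count(mask) * prod(sp)
  area <- coarea_surface(mask$values != 0, sp)
  sphericity <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / area
  # boundary voxels: in mask, with a 6-neighbour outside
  m <- mask$values != 0
  boundary <- which(m & neighbour_any(!m))
  if (length(boundary) == 0L) boundary <- which(m)  # single-voxel masks etc.
  idx <- arrayInd(boundary, dim(m))
  pts <- sweep(idx, 2, sp, `*`)
  maxd <- if (nrow(pts) == 1L) 0 else {
    d2 <- as.matrix(stats::dist(pts))
    max(d2)
  }
  c(VoxelVolume_mm3 = vol, SurfaceArea_mm2 = area,
    Sphericity = sphericity, Maximum3DDiameter = maxd)
}

#' Co-area surface estimate: integral of |grad u| of the smoothed indicator
#' @noRd
coarea_surface <- function(m, spacing_mm) {
  u <- m + 0
  k <- c(0.25, 0.5, 0.25)
  d <- dim(u)
  for (ax in 1:3) {
    if (d[ax] < 3L) next
    perm <- c(ax, setdiff(1:3, ax))
    M <- aperm(u, perm)
    dim(M) <- c(d[ax], length(M) / d[ax])
    n <- d[ax]
    i0 <- c(1L, seq_len(n - 1L)); i2 <- c(seq_len(n - 1L) + 1L, n)
    out <- k[1] * M[i0, , drop = FALSE] + k[2] * M + k[3] * M[i2, , drop = FALSE]
    dim(out) <- d[perm]
    u <- aperm(out, order(perm))
  }
  grad2 <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 3L) next
    up <- vector("list", 1)
    plus <- shift_array(u, as.integer(1:3 == ax), fill = NA)
    minus <- shift_array(u, -as.integer(1:3 == ax), fill = NA)
    g <- (plus - minus) / (2 * spacing_mm[ax])
    g[is.na(g)] <- 0
    grad2 <- grad2 + g^2
  }
  sum(sqrt(grad2)) * prod(spacing_mm)
}

glcm_feature_names <- c("Contrast", "Correlation", "JointEntropy", "Idm")

# the 13 unique 3-D direction offsets (first nonzero component positive)
glcm_offsets <- local({
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  as.matrix(offs[keep, ])
})

#' Gray-level co-occurrence features
#'
#' Intensities inside the mask are discretized with a fixed bin width (edges
#' anchored at the in-mask minimum, so the features are invariant to a
#' constant intensity shift). Co-occurrences are accumulated over the 13
#' unique 3-D directions at the given voxel distance, symmetrized, and
#' normalized to sum 1. Features: Contrast, Correlation, JointEntropy (bits),
#' Idm (inverse difference moment, homogeneity).
#'
#' A region with a single occupied gray level returns the defined fallback
#' Contrast = 0, Idm = 1, and `Correlation = NA` (undefined; dropped at the
#' cohort level).
#'
#' @param volume a `voxel_volume`.
#' @param mask a `binary_mask` on the same grid.
#' @param bin_width discretization bin width (z-score units).
#' @param distance co-occurrence distance in voxels.
#' @return named numeric vector of the 4 features.
#' @export
glcm_features <- function(volume, mask, bin_width = 0.25, distance = 1L) {
  stopifnot_same_grid(volume, mask)
  inside <- mask$values != 0
  if (!any(inside)) stop("glcm_features: empty mask")
  vals <- volume$values[inside]
  g <- array(0L, dim(volume$values))
  g[inside] <- discretize_fixed_width(vals, bin_width)
  K <- max(g)
  if (K == 1L) {
    return(c(Contrast = 0, Correlation = NA_real_, JointEntropy = 0, Idm = 1))
  }
  counts <- numeric(K * K)
  for (r in seq_len(nrow(glcm_offsets))) {
    off <- glcm_offsets[r, ] * as.integer(distance)
    gj <- shift_array(g, off, fill = 0L)
    ok <- g > 0L & gj > 0L
    if (!any(ok)) next
    counts <- counts + tabulate(g[ok] + (gj[ok] - 1L) * K, nbins = K * K)
  }
  P <- matrix(counts, K, K)
  P <- P + t(P)
  if (sum(P) == 0) stop("glcm_features: no co-occurring voxel pairs in mask")
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(K) * px)
  sg2 <- sum((seq_len(K) - mu)^2 * px)
  contrast <- sum(P * (i - j)^2)
  correlation <- if (sg2 > 0) (sum(P * i * j) - mu^2) / sg2 else NA_real_
  nz <- P[P > 0]
  joint_entropy <- -sum(nz * log2(nz))
  idm <- sum(P / (1 + (i - j)^2))
  c(Contrast = contrast, Correlation = correlation,
    JointEntropy = joint_entropy, Idm = idm)
}

#' Extract the radiomic feature row of one lesion
#'
#' Computes first-order and GLCM features for both regions (GTV and 3 mm
#' margin) on the original and wavelet.LLL image channels, plus GTV shape
#' features, under canonical names. The image is expected to be preprocessed
#' (isotropically resampled, z-score normalized).
#'
#' @param image preprocessed `voxel_volume`.
#' @param gtv nonempty GTV `binary_mask`.
#' @param margin nonempty margin `binary_mask`.
#' @param bin_width discretization bin width for Entropy/GLCM.
#' @param lesion_id optional id used in error messages.
#' @param lll optional precomputed `wavelet_lll(image)` (reused across
#'   contour variants of one lesion).
#' @return named numeric vector (one feature-table row).
#' @export
extract_lesion_features <- function(image, gtv, margin, bin_width = 0.25,
                                    lesion_id = NULL, lll = NULL) {
  ctx <- if (is.null(lesion_id)) "" else sprintf(" [lesion %s]", lesion_id)
  tryCatch({
    stopifnot_same_grid(image, gtv, "gtv")
    stopifnot_same_grid(image, margin, "margin")
    if (is.null(lll)) lll <- wavelet_lll(image)
    channels <- list(original = image, wavelet.LLL = lll)
    regions <- list(GTV = gtv, Margin = margin)
    out <- numeric(0)
    for (rg in names(regions)) {
      inside <- regions[[rg]]$values != 0
      if (!any(inside)) stop(sprintf("empty %s mask", rg))
      for (ch in names(channels)) {
        vals <- channels[[ch]]$values[inside]
        fo <- first_order(vals, bin_width = bin_width)
        names(fo) <- vapply(names(fo), function(nm)
          feature_name(rg, ch, "firstorder", nm), character(1))
        gl <- glcm_features(channels[[ch]], regions[[rg]], bin_width = bin_width)
        names(gl) <- vapply(names(gl), function(nm)
          feature_name(rg, ch, "glcm", nm), character(1))
        out <- c(out, fo, gl)
      }
    }
    sh <- shape_features(gtv)
    names(sh) <- vapply(names(sh), function(nm)
      feature_name("GTV", "original", "shape", nm), character(1))
    c(out, sh)
  }, error = function(e) stop(conditionMessage(e), ctx, call. = FALSE))
}

#' Dose-volume histogram summaries
#'
#' `Dx` is the dose received by at least x% of the masked volume, i.e. the
#' (100 - x) percentile of the in-mask dose distribution with linear
#' interpolation; plus the minimum, maximum, and mean dose.
#'
#' @param dose a `voxel_volume` of dose in Gy.
#' @param mask nonempty `binary_mask` on the same grid.
#' @return named numeric vector `Dmin, Dmax, Dmean, D50, D98, D2` (Gy),
#'   satisfying Dmin <= D98 <= D50 <= D2 <= Dmax.
#' @export
dvh_metrics <- function(dose, mask) {
  stopifnot_same_grid(dose, mask)
  inside <- mask$values != 0
  if (!any(inside)) stop("dvh_metrics: empty mask")
  dv <- dose$values[inside]
  q <- stats::quantile(dv, c(0.02, 0.50, 0.98), names = FALSE, type = 7)
  c(Dmin = min(dv), Dmax = max(dv), Dmean = mean(dv),
    D50 = q[2], D98 = q[1], D2 = q[3])
}

#' Biologically effective dose
#'
#' BED = D (1 + d / (alpha/beta)) with dose per fraction d = D / n, used to
#' compare fractionation schemes (e.g. single-fraction radiosurgery at 20 Gy
#' vs 51 Gy in 12 fractions) at a tissue-specific alpha/beta ratio.
#'
#' @param total_dose_gy total physical dose D in Gy (> 0).
#' @param n_fractions number of fractions n (> 0).
#' @param alpha_beta_gy alpha/beta ratio in Gy (> 0), e.g. 10 for tumor,
#'   2 for late-responding normal tissue.
#' @return BED in Gy.
#' @export
compute_bed <- function(total_dose_gy, n_fractions, alpha_beta_gy) {
  if (any(total_dose_gy <= 0) || any(n_fractions <= 0) || any(alpha_beta_gy <= 0)) {
    stop("all arguments to compute_bed must be > 0")
  }
  d <- total_dose_gy / n_fractions
  total_dose_gy * (1 + d / alpha_beta_gy)
}
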