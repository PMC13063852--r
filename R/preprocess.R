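#' Resample a volume to isotropic voxels
#'
#' Standardization step before feature extraction: the grid is resampled to a
#' cubic voxel of side `target_mm` (default 1 mm). The new grid keeps the
#' input origin; its size is `ceiling(extent / target_mm)` per axis so the
#' physical extent is preserved to within one voxel. Images use trilinear
#' interpolation, masks nearest-neighbour (and `binary_mask` inputs default to
#' nearest regardless of `interpolation`).
#'
#' @param volume a `voxel_volume` or `binary_mask`.
#' @param target_mm target isotropic voxel length in mm (> 0).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return a resampled `voxel_volume` (or `binary_mask` for mask input).
#' @export
resample_isotropic <- function(volume, target_mm = 1.0,
                               interpolation = c("linear", "nearest")) {
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0) {
    stop("`target_mm` must be a single positive number")
  }
  interpolation <- match.arg(interpolation)
  if (is_binary_mask(volume)) interpolation <- "nearest"

  d <- dim(volume$values)
  extent <- d * volume$spacing_mm
  new_d <- pmax(1L, as.integer(ceiling(extent / target_mm - 1e-9)))

  # continuous source indices of the new voxel centers (center k at
  # origin + (k-1)*target on each axis)
  ci <- lapply(1:3, function(ax) {
    (seq_len(new_d[ax]) - 1) * target_mm / volume$spacing_mm[ax] + 1
  })
  gx <- rep(ci[[1]], times = new_d[2] * new_d[3])
  gy <- rep(rep(ci[[2]], each = new_d[1]), times = new_d[3])
  gz <- rep(ci[[3]], each = new_d[1] * new_d[2])

  vals <- if (interpolation == "nearest") {
    ix <- pmin(pmax(round(gx), 1), d[1])
    iy <- pmin(pmax(round(gy), 1), d[2])
    iz <- pmin(pmax(round(gz), 1), d[3])
    volume$values[cbind(ix, iy, iz)]
  } else {
    interp_trilinear(volume$values, gx, gy, gz)
  }
  out <- array(vals, dim = new_d)
  if (is_binary_mask(volume)) {
    binary_mask(out, spacing_mm = rep(target_mm, 3), origin_mm = volume$origin_mm)
  } else {
    voxel_volume(out, spacing_mm = rep(target_mm, 3), origin_mm = volume$origin_mm)
  }
}

#' Trilinear interpolation at continuous array indices (clamped to borders)
#' @noRd
interp_trilinear <- function(arr, x, y, z) {
  d <- dim(arr)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2]); z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(y), d[2] - 1L); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(z), d[3] - 1L); z0 <- pmax(z0, 1)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  g <- function(i, j, k) arr[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * g(x0, y0, z0) + fx * g(x1, y0, z0)) +
                fy      * ((1 - fx) * g(x0, y1, z0) + fx * g(x1, y1, z0))) +
    fz      * ((1 - fy) * ((1 - fx) * g(x0, y0, z1) + fx * g(x1, y0, z1)) +
                 fy      * ((1 - fx) * g(x0, y1, z1) + fx * g(x1, y1, z1)))
}

#' Z-score normalize intensities within a brain mask
#'
#' Centers and scales the whole volume by the mean and sample standard
#' deviation (n - 1) of the voxels inside `brain_mask`, so the in-mask
#' distribution has mean 0 and SD 1; voxels outside the mask are mapped with
#' the same affine transform.
#'
#' @param volume a `voxel_volume`.
#' @param brain_mask a `binary_mask` on the same grid, nonempty.
#' @return the normalized `voxel_volume`.
#' @export
zscore_normalize <- function(volume, brain_mask) {
  stopifnot_same_grid(volume, brain_mask, "brain_mask")
  inside <- brain_mask$values != 0
  if (!any(inside)) stop("brain mask is empty")
  v <- volume$values[inside]
  m <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) stop("degenerate intensity distribution")
  voxel_volume((volume$values - m) / s, volume$spacing_mm, volume$origin_mm)
}
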