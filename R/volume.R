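#' Voxel volumes and binary masks
#'
#' A `voxel_volume` is a 3-D scalar grid with a physical voxel spacing and an
#' origin, the common carrier for images and dose grids. A `binary_mask` is a
#' `voxel_volume` whose values are restricted to \{0, 1\} and which lives on the
#' same grid as the image it refers to.
#'
#' @param values numeric 3-D array.
#' @param spacing_mm positive numeric length-3 voxel spacing in mm.
#' @param origin_mm numeric length-3 physical position of the first voxel
#'   center in mm.
#' @return An object of class `voxel_volume` (a list with elements `values`,
#'   `spacing_mm`, `origin_mm`).
#' @export
voxel_volume <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  if (any(!is.finite(values))) stop("`values` must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 strictly positive numbers")
  }
  if (length(origin_mm) != 3L) stop("`origin_mm` must have length 3")
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "voxel_volume")
}

#' @rdname voxel_volume
#' @export
binary_mask <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (is.logical(values)) values <- values + 0L
  if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1")
  v <- voxel_volume(values, spacing_mm, origin_mm)
  class(v) <- c("binary_mask", "voxel_volume")
  v
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Check that two volumes share a grid
#' @noRd
stopifnot_same_grid <- function(a, b, what = "mask") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6 ||
      max(abs(a$origin_mm - b$origin_mm)) > 1e-6) {
    stop(sprintf("%s is not on the same grid as the volume", what))
  }
  invisible(TRUE)
}

mask_count <- function(mask) sum(mask$values != 0)

voxel_volume_mm3 <- function(vol) prod(vol$spacing_mm)

#' Read / write volumes as NIfTI
#'
#' Images are stored as 32-bit float, masks as unsigned 8-bit. The voxel
#' spacing round-trips through the NIfTI pixdim; the origin is kept at the
#' grid corner (all volumes of one lesion share a grid, so no further spatial
#' metadata is needed).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param mask logical; read as a `binary_mask`?
#' @return `read_volume()` returns a `voxel_volume` or `binary_mask`;
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3 - length(spacing)))
  arr <- array(as.numeric(img), dim = dim(img))
  if (mask) binary_mask(round(arr), spacing_mm = spacing[1:3])
  else voxel_volume(arr, spacing_mm = spacing[1:3])
}

#' @rdname read_volume
#' @param vol a `voxel_volume` or `binary_mask`.
#' @export
write_volume <- function(vol, path) {
  datatype <- if (is_binary_mask(vol)) "uint8" else "float"
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Shift an array by an integer voxel offset
#'
#' `out[i, j, k] = x[i + off1, j + off2, k + off3]`, filling with `fill` where
#' the source index falls outside the grid.
#' @noRd
shift_array <- function(x, offset, fill = 0) {
  d <- dim(x)
  out <- array(fill, dim = d)
  src_from <- pmax(1L, 1L + offset)
  src_to <- pmin(d, d + offset)
  if (any(src_from > src_to)) return(out)
  dst_from <- src_from - offset
  dst_to <- src_to - offset
  out[dst_from[1]:dst_to[1], dst_from[2]:dst_to[2], dst_from[3]:dst_to[3]] <-
    x[src_from[1]:src_to[1], src_from[2]:src_to[2], src_from[3]:src_to[3]]
  out
}

#' Exact squared Euclidean distance transform
#'
#' For every voxel, the squared physical distance (mm^2) to the nearest voxel
#' center where `seed` is TRUE. Separable lower-envelope computation
#' (Felzenszwalb & Huttenlocher), one min-plus pass per axis, exact for
#' anisotropic spacing. Voxels are identified with their centers.
#'
#' @param seed logical 3-D array (or 0/1).
#' @param spacing_mm voxel spacing.
#' @return numeric array of squared distances; `Inf` everywhere if no seed.
#' @keywords internal
edt_squared <- function(seed, spacing_mm = c(1, 1, 1)) {
  d <- dim(seed)
  D <- array(ifelse(seed != 0, 0, Inf), dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) next
    t2 <- spacing_mm[ax]^2
    perm <- c(ax, setdiff(1:3, ax))
    M <- aperm(D, perm)
    dim(M) <- c(n, length(M) / n)
    out <- matrix(Inf, n, ncol(M))
    idx <- seq_len(n)
    for (j in idx) {
      fj <- M[j, ]
      if (!any(is.finite(fj))) next
      out <- pmin(out, (idx - j)^2 * t2 + rep(fj, each = n))
    }
    dim(out) <- d[perm]
    D <- aperm(out, order(perm))
  }
  D
}

#' Distance (mm) from every voxel to the nearest mask voxel
#' @keywords internal
distance_to_mask <- function(mask) {
  sqrt(edt_squared(mask$values != 0, mask$spacing_mm))
}
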