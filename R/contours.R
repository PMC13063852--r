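#' Morphological contour perturbation with a physical ball element
#'
#' Erodes or dilates a binary mask with a Euclidean ball of radius
#' `radius_mm`, realized by thresholding an exact distance transform so the
#' element is isotropic in physical units regardless of voxel anisotropy.
#' Used to emulate inter-observer contouring variability:
#' `dilate(v) = {x : d(x, mask) <= r}`, `erode(v) = {x in mask : d(x, bg) > r}`.
#' Erosion that would empty the mask falls back to the single voxel deepest
#' inside the mask (first in array order on ties), so every variant keeps at
#' least one voxel.
#'
#' @param mask nonempty `binary_mask`.
#' @param mode `"erode"`, `"dilate"`, or `"identity"`.
#' @param radius_mm perturbation radius in mm (>= 0).
#' @return a `binary_mask` on the same grid.
#' @export
perturb_contour <- function(mask, mode = c("erode", "dilate", "identity"),
                            radius_mm = 1.0) {
  mode <- match.arg(mode)
  if (mask_count(mask) == 0L) stop("input mask is empty")
  if (!is.numeric(radius_mm) || radius_mm < 0) stop("`radius_mm` must be >= 0")
  if (mode == "identity" || radius_mm == 0) {
    return(binary_mask(mask$values, mask$spacing_mm, mask$origin_mm))
  }
  r2 <- radius_mm^2 + 1e-9
  if (mode == "dilate") {
    d2 <- edt_squared(mask$values != 0, mask$spacing_mm)
    out <- (d2 <= r2) + 0L
  } else {
    d2bg <- edt_squared(mask$values == 0, mask$spacing_mm)
    out <- ((mask$values != 0) & (d2bg > r2)) + 0L
    if (sum(out) == 0L) {
      deepest <- which.max(ifelse(mask$values != 0, d2bg, -1))
      out <- array(0L, dim(mask$values))
      out[deepest] <- 1L
    }
  }
  binary_mask(out, mask$spacing_mm, mask$origin_mm)
}

#' Randomly jitter a contour surface by one voxel
#'
#' The stand-in for an independent (e.g. learned) segmentation: each voxel of
#' the inner boundary (mask voxels with a 6-neighbour outside) is removed with
#' probability `prob`, and each voxel of the outer boundary (background voxels
#' with a 6-neighbour inside) is added with probability `prob`. Seeded and
#' deterministic; never returns an empty mask.
#'
#' @param mask nonempty `binary_mask`.
#' @param prob flip probability per surface voxel.
#' @param seed integer seed.
#' @return a `binary_mask`.
#' @export
jitter_contour <- function(mask, prob = 0.5, seed = 1L) {
  if (mask_count(mask) == 0L) stop("input mask is empty")
  m <- mask$values != 0
  nb <- neighbour_any(!m)        # has a background 6-neighbour
  inner <- m & nb
  outer <- (!m) & neighbour_any(m)
  out <- m
  with_seed(seed, {
    ii <- which(inner); oo <- which(outer)
    out[ii[stats::runif(length(ii)) < prob]] <- FALSE
    out[oo[stats::runif(length(oo)) < prob]] <- TRUE
  })
  if (!any(out)) out <- m  # degenerate tiny mask: keep original
  binary_mask(out + 0L, mask$spacing_mm, mask$origin_mm)
}

#' Any 6-neighbour TRUE?
#' @noRd
neighbour_any <- function(m) {
  out <- array(FALSE, dim(m))
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    out <- out | (shift_array(m + 0L, off, fill = 0) != 0)
  }
  out
}

#' Peritumoral margin mask
#'
#' The margin is the shell `dilate(gtv, width_mm) \ gtv`, optionally clipped
#' to the brain mask — the candidate site of microscopic infiltration around
#' the enhancing lesion (default width 3 mm).
#'
#' @param gtv nonempty `binary_mask` of the gross tumor volume.
#' @param width_mm margin width in mm (> 0), default 3.
#' @param brain_mask optional `binary_mask`; required when `clip_to_brain`.
#' @param clip_to_brain intersect the margin with the brain mask?
#' @return a `binary_mask` disjoint from `gtv`.
#' @export
make_margin <- function(gtv, width_mm = 3.0, brain_mask = NULL,
                        clip_to_brain = !is.null(brain_mask)) {
  if (mask_count(gtv) == 0L) stop("GTV mask is empty")
  if (!is.numeric(width_mm) || width_mm <= 0) stop("`width_mm` must be > 0")
  dil <- perturb_contour(gtv, "dilate", width_mm)
  out <- dil$values * (gtv$values == 0)
  if (clip_to_brain) {
    if (is.null(brain_mask)) stop("`brain_mask` required when clip_to_brain = TRUE")
    stopifnot_same_grid(gtv, brain_mask, "brain_mask")
    out <- out * (brain_mask$values != 0)
  }
  if (sum(out) == 0L) stop("lesion at mask boundary: margin empty after clipping")
  binary_mask(out, gtv$spacing_mm, gtv$origin_mm)
}

#' The four contour variants of a lesion
#'
#' Manual contour plus three perturbed variants emulating inter-observer
#' variability: erosion, dilation (ball radius `perturb_mm`) and a seeded
#' one-voxel boundary jitter. The contour-dependence filter compares features
#' between the manual mask and each perturbed variant.
#'
#' @param manual the manual GTV `binary_mask`.
#' @param perturb_mm erosion/dilation radius in mm (default 1).
#' @param jitter_seed seed for the jitter variant.
#' @param jitter_prob surface flip probability for the jitter variant.
#' @return named list of `binary_mask`: `manual`, `eroded`, `dilated`,
#'   `jittered`. The identity perturbation equals `manual` by construction.
#' @export
contour_variants <- function(manual, perturb_mm = 1.0, jitter_seed = 1L,
                             jitter_prob = 0.5) {
  list(
    manual   = perturb_contour(manual, "identity"),
    eroded   = perturb_contour(manual, "erode", perturb_mm),
    dilated  = perturb_contour(manual, "dilate", perturb_mm),
    jittered = jitter_contour(manual, prob = jitter_prob, seed = jitter_seed)
  )
}
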