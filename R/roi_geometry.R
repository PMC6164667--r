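#' ROI mask container
#'
#' A boolean grid aligned to a parent volume plus provenance: how the mask
#' was built (`circle2d`, `sphere3d` or `external`), its seed point, radius
#' and, for single-slice circles, which grid axis is held fixed.
#'
#' All voxel coordinates in this package are 1-based array indices, matching
#' R's array semantics. Distances are measured between voxel centers, in
#' voxel units, isotropically (anisotropic slice thickness is deliberately
#' ignored: radii are specified "in pixels").
#'
#' @param mask 3D logical array.
#' @param shape_kind one of "circle2d", "sphere3d", "external".
#' @param center integer length-3 voxel index (1-based), or NA for external.
#' @param radius_vox positive radius in voxel units, or NA for external.
#' @param slice_axis for circle2d, the grid axis held fixed (1, 2 or 3).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, shape_kind, center = rep(NA_integer_, 3),
                     radius_vox = NA_real_, slice_axis = NA_integer_) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("'mask' must be a 3D logical array")
  if (!any(mask))
    stop("ROI mask is empty (no true voxels)")
  shape_kind <- match.arg(shape_kind, c("circle2d", "sphere3d", "external"))
  if (shape_kind == "circle2d") {
    ax <- which(apply(mask, slice_axis, any))
    if (length(ax) != 1L)
      stop("circle2d mask must occupy a single slice along slice_axis")
  }
  structure(list(mask = mask, shape_kind = shape_kind,
                 center = as.integer(center), radius_vox = radius_vox,
                 slice_axis = as.integer(slice_axis)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", x$shape_kind, ", ", sum(x$mask), " voxels",
      if (!is.na(x$radius_vox)) paste0(", r = ", x$radius_vox), "\n", sep = "")
  invisible(x)
}

check_center <- function(vol_shape, center) {
  vol_shape <- as.integer(vol_shape)
  center <- as.integer(center)
  if (length(vol_shape) != 3L || any(vol_shape < 1L))
    stop("'vol_shape' must be 3 positive integers")
  if (length(center) != 3L || any(center < 1L) || any(center > vol_shape))
    stop("'center' must lie inside the volume grid")
  list(vol_shape = vol_shape, center = center)
}

#' Circular (single-slice) ROI mask
#'
#' Builds a disc of radius `radius_vox` around `center` in the slice
#' perpendicular to `slice_axis` (by default axis 2, the coronal axis under
#' the standard sagittal/coronal/axial axis labelling). A voxel belongs to
#' the disc when the Euclidean distance between voxel centers, over the two
#' varying axes, is `<= radius_vox`. Discs clipped by the volume boundary are
#' rejected rather than truncated, since a partial ROI would silently change
#' its feature statistics.
#'
#' @param vol_shape integer length-3 grid dimensions.
#' @param center integer length-3 voxel index (1-based).
#' @param radius_vox positive radius in voxel units.
#' @param slice_axis grid axis held fixed (1, 2 or 3); default 2.
#' @return A [roi_mask()] with `shape_kind = "circle2d"`.
#' @export
circular_mask <- function(vol_shape, center, radius_vox, slice_axis = 2L) {
  g <- check_center(vol_shape, center)
  if (!is.numeric(radius_vox) || length(radius_vox) != 1L || radius_vox <= 0)
    stop("'radius_vox' must be a positive number")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("'slice_axis' must be 1, 2 or 3")
  vary <- setdiff(1:3, slice_axis)
  rint <- floor(radius_vox)
  lo <- g$center[vary] - rint; hi <- g$center[vary] + rint
  if (any(lo < 1L) || any(hi > g$vol_shape[vary]))
    stop("circular ROI (r = ", radius_vox, ") extends outside the volume; ",
         "partial ROIs are refused")
  mask <- array(FALSE, dim = g$vol_shape)
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2]))
  d2 <- (idx[, 1] - g$center[vary[1]])^2 + (idx[, 2] - g$center[vary[2]])^2
  idx <- idx[d2 <= radius_vox^2, , drop = FALSE]
  full <- matrix(g$center[slice_axis], nrow(idx), 3)
  full[, vary[1]] <- idx[, 1]; full[, vary[2]] <- idx[, 2]
  mask[full] <- TRUE
  roi_mask(mask, "circle2d", center = g$center, radius_vox = radius_vox,
           slice_axis = slice_axis)
}

#' Spherical ROI mask
#'
#' As [circular_mask()], but over all three axes: a ball of voxels whose
#' center-to-center Euclidean distance from `center` is `<= radius_vox`.
#'
#' @inheritParams circular_mask
#' @return A [roi_mask()] with `shape_kind = "sphere3d"`.
#' @export
spherical_mask <- function(vol_shape, center, radius_vox) {
  g <- check_center(vol_shape, center)
  if (!is.numeric(radius_vox) || length(radius_vox) != 1L || radius_vox <= 0)
    stop("'radius_vox' must be a positive number")
  rint <- floor(radius_vox)
  lo <- g$center - rint; hi <- g$center + rint
  if (any(lo < 1L) || any(hi > g$vol_shape))
    stop("spherical ROI (r = ", radius_vox, ") extends outside the volume; ",
         "partial ROIs are refused")
  mask <- array(FALSE, dim = g$vol_shape)
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  d2 <- (idx[, 1] - g$center[1])^2 + (idx[, 2] - g$center[2])^2 +
    (idx[, 3] - g$center[3])^2
  mask[idx[d2 <= radius_vox^2, , drop = FALSE]] <- TRUE
  roi_mask(mask, "sphere3d", center = g$center, radius_vox = radius_vox)
}

#' Concentric circular and spherical ROIs around one seed point
#'
#' Builds one disc and one ball per radius, all sharing the seed point, as
#' used for hippocampal analysis with radii 3, 5 and 8 voxels: 6 ROIs per
#' seed point (3 circles + 3 spheres), hence 12 per subject with left and
#' right seeds.
#'
#' @inheritParams circular_mask
#' @param radii strictly increasing positive radii (default `c(3, 5, 8)`).
#' @return A list with elements `circles` and `spheres`, each a list of
#'   [roi_mask()] objects in radius order.
#' @export
concentric_rois <- function(vol_shape, center, radii = c(3, 5, 8),
                            slice_axis = 2L) {
  radii <- as.numeric(radii)
  if (length(radii) < 1L || any(radii <= 0) || any(diff(radii) <= 0))
    stop("'radii' must be strictly increasing positive numbers")
  list(circles = lapply(radii, function(r)
         circular_mask(vol_shape, center, r, slice_axis = slice_axis)),
       spheres = lapply(radii, function(r)
         spherical_mask(vol_shape, center, r)))
}

#' Load an externally supplied binary ROI mask
#'
#' Accepts a NIfTI image of 0/1 values aligned to the parent volume, in place
#' of interactive free-hand segmentation.
#'
#' @param path NIfTI mask path.
#' @param vol_shape expected grid dimensions of the parent volume.
#' @return A [roi_mask()] with `shape_kind = "external"`.
#' @export
load_external_mask <- function(path, vol_shape) {
  vol <- read_volume(path)
  vol_shape <- as.integer(vol_shape)
  if (!identical(dim(vol$data), vol_shape))
    stop("mask shape (", paste(dim(vol$data), collapse = "x"),
         ") does not match volume shape (",
         paste(vol_shape, collapse = "x"), ")")
  vals <- unique(as.vector(vol$data))
  if (!all(vals %in% c(0, 1)))
    stop("external mask must be binary (0/1); found other values")
  if (!any(vol$data == 1))
    stop("external mask is empty")
  roi_mask(array(vol$data == 1, dim = vol_shape), "external")
}
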