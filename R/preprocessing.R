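#' Normalize ROI intensities by the mu +/- 3 sigma rule
#'
#' Computes the mean and (population) standard deviation of the in-mask
#' intensities and rejects voxels falling outside `[mu - k*sigma,
#' mu + k*sigma]` with `k = sigma_multiplier` (default 3). Rejection removes
#' the voxel from the ROI grid (it becomes a hole that later breaks
#' co-occurrence pairs and runs); surviving intensities are left unchanged —
#' this is outlier rejection, not clipping.
#'
#' Results are returned on the bounding box of the mask, which is the grid
#' all downstream texture matrices operate on.
#'
#' @param volume a [tex_volume()].
#' @param mask a [roi_mask()] aligned to `volume`.
#' @param sigma_multiplier half-width of the acceptance interval in standard
#'   deviations; default 3.
#' @return A list with `values` (numeric array over the mask bounding box),
#'   `valid` (logical array: in-mask and inside the acceptance interval),
#'   `mu`, `sigma`, and `bbox` (3x2 matrix of bounding-box index ranges in
#'   the parent grid).
#' @export
normalize_mu3sigma <- function(volume, mask, sigma_multiplier = 3) {
  stopifnot(inherits(volume, "tex_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$mask)))
    stop("volume and mask dimensions differ")
  if (!is.numeric(sigma_multiplier) || sigma_multiplier <= 0)
    stop("'sigma_multiplier' must be positive")
  m <- mask$mask
  if (!any(m)) stop("empty ROI mask")
  vals_in <- volume$data[m]
  mu <- mean(vals_in)
  sigma <- sqrt(mean((vals_in - mu)^2))  # population formula
  bbox <- vapply(1:3, function(a) {
    ix <- which(apply(m, a, any))
    c(min(ix), max(ix))
  }, numeric(2))
  bbox <- t(bbox)  # 3 x 2
  sub <- function(arr) arr[bbox[1, 1]:bbox[1, 2],
                           bbox[2, 1]:bbox[2, 2],
                           bbox[3, 1]:bbox[3, 2], drop = FALSE]
  values <- sub(volume$data)
  inmask <- sub(m)
  valid <- inmask & values >= mu - sigma_multiplier * sigma &
    values <= mu + sigma_multiplier * sigma
  # the mean itself is always inside the interval, so >= 1 voxel survives
  stopifnot(any(valid))
  list(values = values, valid = valid, mu = mu, sigma = sigma, bbox = bbox)
}

#' Quantized ROI container
#'
#' Integer gray levels in `1..n_levels` over the ROI bounding box, with
#' invalid cells (outside the mask or rejected by normalization) marked.
#' Invalid cells never contribute to any downstream matrix.
#'
#' @param levels integer array; NA at invalid cells.
#' @param valid logical array, same shape.
#' @param n_levels number of gray levels Ng.
#' @return An object of class `quantized_roi` with fields `levels`, `valid`,
#'   `n_levels`, `n_valid`.
#' @export
quantized_roi <- function(levels, valid, n_levels) {
  stopifnot(is.array(levels), is.array(valid),
            identical(dim(levels), dim(valid)))
  n_valid <- sum(valid)
  if (n_valid < 1L) stop("quantized ROI has no valid cells")
  lv <- levels[valid]
  if (any(is.na(lv)) || any(lv < 1L) || any(lv > n_levels))
    stop("valid cells must carry levels in 1..n_levels")
  structure(list(levels = levels, valid = valid,
                 n_levels = as.integer(n_levels), n_valid = n_valid),
            class = "quantized_roi")
}

#' Quantize ROI intensities to Ng gray levels
#'
#' Uniform binning of the valid intensities onto `1..n_levels`:
#' `level = min(floor((x - xmin) * Ng / (xmax - xmin)) + 1, Ng)` with
#' `xmin`/`xmax` taken over valid cells. A constant ROI (xmax == xmin) maps
#' every valid cell to level 1. The default of 64 levels (6 bits) trades
#' intensity resolution for co-occurrence statistics that are dense enough
#' to be stable at hippocampal ROI sizes.
#'
#' Because the binning depends only on the rank position of each value inside
#' `[xmin, xmax]`, any positive affine rescaling of the intensities yields an
#' identical level grid, making all downstream features invariant to scanner
#' gain and offset.
#'
#' @param values numeric array (ROI bounding box).
#' @param valid logical array marking cells to quantize.
#' @param n_levels number of gray levels, >= 2 (default 64).
#' @return A [quantized_roi()].
#' @export
quantize <- function(values, valid, n_levels = 64L) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2)
    stop("'n_levels' must be an integer >= 2")
  n_levels <- as.integer(n_levels)
  if (sum(valid) < 1L) stop("no valid cells to quantize")
  x <- values[valid]
  xmin <- min(x); xmax <- max(x)
  levels <- array(NA_integer_, dim = dim(values))
  if (xmax == xmin) {
    levels[valid] <- 1L
  } else {
    levels[valid] <- pmin(
      as.integer(floor((x - xmin) * n_levels / (xmax - xmin))) + 1L,
      n_levels)
  }
  quantized_roi(levels, valid, n_levels)
}

#' Normalize and quantize a masked ROI in one step
#'
#' @inheritParams normalize_mu3sigma
#' @inheritParams quantize
#' @return A [quantized_roi()].
#' @export
preprocess_roi <- function(volume, mask, n_levels = 64L, sigma_multiplier = 3) {
  norm <- normalize_mu3sigma(volume, mask, sigma_multiplier = sigma_multiplier)
  quantize(norm$values, norm$valid, n_levels = n_levels)
}
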