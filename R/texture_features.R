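#' Direction sets for rotation-invariant matrix averaging
#'
#' GLCM and GLRLM matrices are direction dependent; to obtain orientation-
#' independent features a single matrix per ROI is formed by weighted
#' averaging of the directional matrices.
#'
#' In 2D the four in-plane directions (0, 45, 90, 135 degrees) are averaged
#' with equal weights. In 3D the 13 unique directions of the 26-neighborhood
#' (3 axis, 6 face-diagonal, 4 space-diagonal; antipodal offsets are
#' equivalent because pair counting is symmetric and runs are direction-
#' reversal invariant) are averaged with weights proportional to the inverse
#' Euclidean step length 1/||d||, compensating the different discretization
#' lengths of axis, face-diagonal and space-diagonal steps.
#'
#' @param mode "2d" or "3d".
#' @param slice_axis for 2D, the grid axis held fixed by the ROI slice.
#' @return An object of class `direction_set`: list with `offsets` (list of
#'   integer 3-vectors) and `weights` (positive, summing to 1).
#' @export
directions <- function(mode = c("2d", "3d"), slice_axis = 2L) {
  mode <- match.arg(mode)
  if (mode == "2d") {
    slice_axis <- as.integer(slice_axis)
    if (!slice_axis %in% 1:3) stop("'slice_axis' must be 1, 2 or 3")
    vary <- setdiff(1:3, slice_axis)
    plane <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
    offsets <- lapply(plane, function(d) {
      v <- c(0L, 0L, 0L)
      v[vary] <- d
      v
    })
    weights <- rep(1 / 4, 4)
  } else {
    offsets <- list()
    for (d1 in -1:1) for (d2 in -1:1) for (d3 in -1:1) {
      d <- c(d1, d2, d3)
      if (all(d == 0L)) next
      # keep one representative per antipodal pair: first nonzero positive
      nz <- which(d != 0L)[1]
      if (d[nz] < 0L) next
      offsets <- c(offsets, list(as.integer(d)))
    }
    lens <- vapply(offsets, function(d) sqrt(sum(d^2)), numeric(1))
    weights <- (1 / lens) / sum(1 / lens)
  }
  structure(list(offsets = offsets, weights = weights),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat("<direction_set> ", length(x$offsets), " offsets\n", sep = "")
  invisible(x)
}

# index ranges such that both cell c and c+d lie inside dims
offset_ranges <- function(dims, d) {
  lapply(1:3, function(a) seq.int(max(1L, 1L - d[a]),
                                  min(dims[a], dims[a] - d[a])))
}

#' Gray-level co-occurrence matrix, averaged over directions
#'
#' For each offset `d`, counts pairs of valid cells displaced by `d`
#' (symmetrically, so each pair contributes to both (i,j) and (j,i)),
#' normalizes the directional count matrix to sum 1, and averages the
#' normalized matrices with the direction weights. Invalid cells (rejected
#' by normalization or outside the mask) never form pairs. Directions that
#' contain no valid pair are dropped and the remaining weights renormalized;
#' if no direction has a pair the ROI is degenerate and an error is raised.
#'
#' @param qroi a [quantized_roi()].
#' @param dirs a [directions()] set.
#' @return An object of class `glcm`: list with `p` (Ng x Ng symmetric
#'   probability matrix summing to 1) and `n_levels`.
#' @export
glcm <- function(qroi, dirs) {
  stopifnot(inherits(qroi, "quantized_roi"), inherits(dirs, "direction_set"))
  ng <- qroi$n_levels
  lv <- qroi$levels
  dims <- dim(lv)
  p <- matrix(0, ng, ng)
  wsum <- 0
  for (k in seq_along(dirs$offsets)) {
    d <- dirs$offsets[[k]]
    r <- offset_ranges(dims, d)
    if (any(vapply(r, length, integer(1)) < 1L)) next
    a <- lv[r[[1]], r[[2]], r[[3]], drop = FALSE]
    b <- lv[r[[1]] + d[1], r[[2]] + d[2], r[[3]] + d[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- matrix(tabulate(a[ok] + (b[ok] - 1L) * ng, nbins = ng * ng),
                     ng, ng)
    counts <- counts + t(counts)
    p <- p + dirs$weights[k] * counts / sum(counts)
    wsum <- wsum + dirs$weights[k]
  }
  if (wsum == 0)
    stop("degenerate ROI: no valid co-occurrence pair in any direction")
  structure(list(p = p / wsum, n_levels = ng), class = "glcm")
}

#' GLCM feature panel (9 features)
#'
#' With `p(i,j)` the co-occurrence probabilities, marginal `p_x(i) = sum_j
#' p(i,j)`, marginal mean `mu = sum_i i p_x(i)` and variance `sigma2`:
#' Energy `= sum p^2`; Contrast `= sum (i-j)^2 p`; Entropy
#' `= -sum_{p>0} p log2 p`; Homogeneity `= sum p / (1+|i-j|)`; Correlation
#' `= (sum i j p - mu^2) / sigma2` (undefined, returned as NA, when
#' `sigma2 = 0`); Sum Average `= sum (i+j) p`; Variance `= sum (i-mu)^2 p`;
#' Dissimilarity `= sum |i-j| p`; Autocorrelation `= sum i j p`.
#'
#' @param g a [glcm()].
#' @return Named numeric vector of the 9 GLCM features.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  p <- g$p
  ng <- g$n_levels
  i <- matrix(seq_len(ng), ng, ng)       # row index = first level
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  sigma2 <- sum((seq_len(ng) - mu)^2 * px)
  pos <- p[p > 0]
  c("Energy" = sum(p^2),
    "Contrast" = sum((i - j)^2 * p),
    "Entropy" = -sum(pos * log2(pos)),
    "Homogeneity" = sum(p / (1 + abs(i - j))),
    "Correlation" = if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2
                    else NA_real_,
    "Sum Average" = sum((i + j) * p),
    "Variance" = sum((i - mu)^2 * p),
    "Dissimilarity" = sum(abs(i - j) * p),
    "Autocorrelation" = sum(i * j * p))
}

# run-length decomposition along one offset: returns matrix of run counts
glrlm_one_direction <- function(lv, d, ng, lmax) {
  dims <- dim(lv)
  n <- length(lv)
  coords <- arrayInd(seq_len(n), dims)
  # scalar step position along the line: coordinate on the first moving axis,
  # signed so each step along d increments it by exactly 1
  a0 <- which(d != 0L)[1]
  t_pos <- coords[, a0] * d[a0]
  key <- coords - outer(t_pos, d)  # line origin, constant within a line
  ord <- order(key[, 1], key[, 2], key[, 3], t_pos)
  lvo <- lv[ord]
  ko <- key[ord, , drop = FALSE]
  newline <- c(TRUE, rowSums(abs(ko[-1, , drop = FALSE] -
                                 ko[-n, , drop = FALSE])) > 0)
  validv <- !is.na(lvo)
  prev_valid <- c(FALSE, validv[-n])
  prev_lv <- c(NA_integer_, lvo[-n])
  is_start <- validv & (newline | !prev_valid |
                        (validv & prev_valid & lvo != prev_lv))
  runid <- cumsum(is_start)
  rid <- runid[validv]
  lens <- tabulate(rid)
  run_level <- lvo[validv][!duplicated(rid)]
  matrix(tabulate(run_level + (pmin(lens, lmax) - 1L) * ng,
                  nbins = ng * lmax), ng, lmax)
}

#' Gray-level run-length matrix, averaged over directions
#'
#' For each offset, scans maximal runs of consecutive valid cells sharing one
#' quantized level along every grid line in that direction (a run breaks at
#' the grid edge, at an invalid cell, and at a level change), builds the
#' run-count matrix `r_d(level, length)`, and averages `sum_d w_d r_d` with
#' the direction weights, giving real-valued averaged counts. Every direction
#' contributes (any valid cell is at least a run of length 1), so the weights
#' need no renormalization.
#'
#' @inheritParams glcm
#' @return An object of class `glrlm`: list with `r` (Ng x Lmax averaged run
#'   counts), `n_runs` (total run weight), `n_voxels` (valid voxel count) and
#'   `n_levels`.
#' @export
glrlm <- function(qroi, dirs) {
  stopifnot(inherits(qroi, "quantized_roi"), inherits(dirs, "direction_set"))
  ng <- qroi$n_levels
  lv <- qroi$levels
  lmax <- max(dim(lv))
  r <- matrix(0, ng, lmax)
  for (k in seq_along(dirs$offsets))
    r <- r + dirs$weights[k] *
      glrlm_one_direction(lv, dirs$offsets[[k]], ng, lmax)
  structure(list(r = r, n_runs = sum(r), n_voxels = qroi$n_valid,
                 n_levels = ng), class = "glrlm")
}

#' GLRLM feature panel (13 features)
#'
#' With `r(i,j)` the averaged run counts, `Nr = sum r`, `Np` the valid voxel
#' count and `rho = r / Nr`: SRE `= sum rho/j^2`; LRE `= sum rho j^2`; GLN
#' `= sum_i (sum_j r)^2 / Nr`; RLN `= sum_j (sum_i r)^2 / Nr`; RP `= Nr/Np`;
#' LGRE `= sum rho/i^2`; HGRE `= sum rho i^2`; SRLGE `= sum rho/(i^2 j^2)`;
#' SRHGE `= sum rho i^2/j^2`; LRLGE `= sum rho j^2/i^2`; LRHGE
#' `= sum rho i^2 j^2`; GLV `= sum rho (i - mu_g)^2` and RLV
#' `= sum rho (j - mu_l)^2` with `mu_g`, `mu_l` the level and length means
#' under `rho`.
#'
#' @param g a [glrlm()].
#' @return Named numeric vector of the 13 GLRLM features.
#' @export
glrlm_features <- function(g) {
  stopifnot(inherits(g, "glrlm"))
  r <- g$r
  nr <- g$n_runs
  if (nr <= 0) stop("GLRLM has no runs")
  rho <- r / nr
  ng <- nrow(r); lmax <- ncol(r)
  i2 <- matrix(seq_len(ng)^2, ng, lmax)
  j2 <- matrix(seq_len(lmax)^2, ng, lmax, byrow = TRUE)
  iM <- matrix(seq_len(ng), ng, lmax)
  jM <- matrix(seq_len(lmax), ng, lmax, byrow = TRUE)
  mu_g <- sum(iM * rho)
  mu_l <- sum(jM * rho)
  c("SRE" = sum(rho / j2),
    "LRE" = sum(rho * j2),
    "GLN" = sum(rowSums(r)^2) / nr,
    "RLN" = sum(colSums(r)^2) / nr,
    "RP" = nr / g$n_voxels,
    "LGRE" = sum(rho / i2),
    "HGRE" = sum(rho * i2),
    "SRLGE" = sum(rho / (i2 * j2)),
    "SRHGE" = sum(rho * i2 / j2),
    "LRLGE" = sum(rho * j2 / i2),
    "LRHGE" = sum(rho * i2 * j2),
    "GLV" = sum(rho * (iM - mu_g)^2),
    "RLV" = sum(rho * (jM - mu_l)^2))
}

#' Global intensity-histogram features (3 features)
#'
#' Population central moments of the quantized levels over valid cells:
#' Global Variance `= E[(x-mu)^2]`, Skewness `= E[(x-mu)^3]/sigma^3` and
#' non-excess Kurtosis `= E[(x-mu)^4]/sigma^4` (a normal distribution gives
#' 3; subtract 3 for excess kurtosis). Skewness and Kurtosis are undefined
#' (NA) for a constant ROI.
#'
#' @param qroi a [quantized_roi()].
#' @return Named numeric vector: Global Variance, Skewness, Kurtosis.
#' @export
histogram_features <- function(qroi) {
  stopifnot(inherits(qroi, "quantized_roi"))
  x <- as.numeric(qroi$levels[qroi$valid])
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  c("Global Variance" = m2,
    "Skewness" = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_,
    "Kurtosis" = if (m2 > 0) mean((x - mu)^4) / m2^2 else NA_real_)
}

#' Extract the 25-feature texture panel from one ROI
#'
#' Runs the full per-ROI pipeline: mu +/- 3 sigma normalization, uniform
#' quantization to `n_levels` gray levels, then the intensity-histogram (3),
#' GLCM (9) and GLRLM (13) feature panels with rotation-invariant direction
#' averaging. The direction mode is inferred from the mask: single-slice
#' circles use the four in-plane 2D directions; spheres and external masks
#' use the thirteen 3D directions.
#'
#' @param volume a [tex_volume()].
#' @param mask a [roi_mask()] aligned to `volume`.
#' @param n_levels gray levels for quantization (default 64).
#' @param sigma_multiplier outlier-rejection half-width (default 3).
#' @param mode "auto" (infer from mask), "2d" or "3d".
#' @return Named numeric vector of length 25 in [feature_names()] order;
#'   entries are NA where a feature is undefined for the ROI (e.g.
#'   Correlation on a constant ROI). A ROI so degenerate that no
#'   co-occurrence pair exists yields NA for all 9 GLCM features.
#' @export
extract_features <- function(volume, mask, n_levels = 64L,
                             sigma_multiplier = 3,
                             mode = c("auto", "2d", "3d")) {
  mode <- match.arg(mode)
  qroi <- preprocess_roi(volume, mask, n_levels = n_levels,
                         sigma_multiplier = sigma_multiplier)
  if (mode == "auto")
    mode <- if (mask$shape_kind == "circle2d") "2d" else "3d"
  dirs <- directions(mode, slice_axis = if (mode == "2d") mask$slice_axis
                                        else 2L)
  hist_f <- histogram_features(qroi)
  glcm_f <- tryCatch(glcm_features(glcm(qroi, dirs)),
                     error = function(e) {
                       out <- rep(NA_real_, 9)
                       names(out) <- feature_names()[4:12]
                       out
                     })
  glrlm_f <- glrlm_features(glrlm(qroi, dirs))
  out <- c(hist_f, glcm_f, glrlm_f)
  stopifnot(identical(names(out), feature_names()))
  out
}
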