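#' Extract the feature table for one subject
#'
#' Builds the concentric circular and spherical ROIs at every seed point and
#' extracts the 25-feature panel for each, yielding one feature-table row per
#' ROI (`2 * length(radii)` rows per seed point). ROI identifiers follow the
#' `ROI<rank>_<side>_<2D|3D>` convention, ROI1 being the smallest radius.
#' A ROI that does not fit inside the volume is skipped with a warning.
#'
#' @param volume a [tex_volume()].
#' @param subject_id,group identifier and group label for the table rows.
#' @param centers data frame with columns `side`, `x`, `y`, `z` (1-based
#'   voxel indices) — the seed points for this subject.
#' @param radii strictly increasing ROI radii in voxels (default c(3, 5, 8)).
#' @param slice_axis grid axis fixed for circular ROIs (default 2, coronal).
#' @param n_levels gray levels for quantization (default 64).
#' @param sigma_multiplier outlier-rejection half-width (default 3).
#' @return Data frame in feature-table layout, one row per ROI.
#' @export
extract_subject_features <- function(volume, subject_id, group, centers,
                                     radii = c(3, 5, 8), slice_axis = 2L,
                                     n_levels = 64L, sigma_multiplier = 3) {
  stopifnot(is.data.frame(centers),
            all(c("side", "x", "y", "z") %in% names(centers)))
  shape <- dim(volume$data)
  rows <- list()
  for (ci in seq_len(nrow(centers))) {
    side <- as.character(centers$side[ci])
    ctr <- c(centers$x[ci], centers$y[ci], centers$z[ci])
    for (ri in seq_along(radii)) {
      for (kind in c("circle", "sphere")) {
        roi_id <- sprintf("ROI%d_%s_%s", ri, side,
                          if (kind == "circle") "2D" else "3D")
        mask <- tryCatch(
          if (kind == "circle")
            circular_mask(shape, ctr, radii[ri], slice_axis = slice_axis)
          else spherical_mask(shape, ctr, radii[ri]),
          error = function(e) {
            warning("skipping ", roi_id, " for ", subject_id, ": ",
                    conditionMessage(e), call. = FALSE)
            NULL
          })
        if (is.null(mask)) next
        fv <- extract_features(volume, mask, n_levels = n_levels,
                               sigma_multiplier = sigma_multiplier)
        row <- data.frame(subject_id = subject_id, group = group,
                          roi_id = roi_id, side = side,
                          shape = if (kind == "circle") "circle2d"
                                  else "sphere3d",
                          radius_vox = radii[ri],
                          stringsAsFactors = FALSE)
        row[feature_names()] <- as.list(unname(fv))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (!length(rows)) stop("no ROI could be extracted for ", subject_id)
  do.call(rbind, rows)
}

#' Extract the feature table for an in-memory phantom cohort
#'
#' Convenience wrapper running [extract_subject_features()] over every
#' subject of a [generate_cohort()] result.
#'
#' @param cohort result of [generate_cohort()].
#' @inheritParams extract_subject_features
#' @return Feature table data frame (one row per subject x ROI).
#' @export
extract_cohort_features <- function(cohort, radii = c(3, 5, 8),
                                    slice_axis = 2L, n_levels = 64L,
                                    sigma_multiplier = 3) {
  tabs <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    sid <- cohort$subjects$subject_id[i]
    extract_subject_features(
      cohort$volumes[[sid]], sid, cohort$subjects$group[i],
      cohort$centers[cohort$centers$subject_id == sid, , drop = FALSE],
      radii = radii, slice_axis = slice_axis, n_levels = n_levels,
      sigma_multiplier = sigma_multiplier)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
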