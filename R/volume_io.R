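#' Volume container
#'
#' A `tex_volume` wraps a 3D intensity array together with its voxel spacing
#' (mm per voxel along each array axis) and a label mapping array axes to
#' anatomical planes. Images are analyzed in their native voxel grid: no
#' resampling or spatial normalization is performed.
#'
#' @param data 3D numeric array of intensities (arbitrary scanner units).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param axis_labels character length-3 mapping each array axis to one of
#'   "sagittal", "coronal", "axial".
#' @return An object of class `tex_volume` with elements `data`, `spacing`
#'   and `axis_labels`.
#' @export
tex_volume <- function(data, spacing = c(1, 1, 1),
                       axis_labels = c("sagittal", "coronal", "axial")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all three dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite numbers")
  axis_labels <- as.character(axis_labels)
  if (length(axis_labels) != 3L)
    stop("'axis_labels' must have length 3")
  structure(list(data = data, spacing = spacing, axis_labels = axis_labels),
            class = "tex_volume")
}

#' @export
print.tex_volume <- function(x, ...) {
  cat("<tex_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.tex_volume <- function(x) dim(x$data)

# Map a NIfTI orientation string (e.g. "LAS") to anatomical plane labels per
# array axis: L/R -> sagittal, A/P -> coronal, S/I -> axial.
orientation_to_labels <- function(orient) {
  if (is.null(orient) || !nzchar(orient) || nchar(orient) < 3L)
    return(c("sagittal", "coronal", "axial"))
  codes <- strsplit(toupper(orient), "")[[1]][1:3]
  lab <- function(ch) switch(ch,
    L = , R = "sagittal",
    A = , P = "coronal",
    S = , I = "axial",
    NA_character_)
  out <- vapply(codes, lab, character(1))
  if (anyNA(out)) c("sagittal", "coronal", "axial") else out
}

#' Read a volumetric MRI image
#'
#' Reads a NIfTI-1/NIfTI-2 image and returns it as a [tex_volume()]. Data are
#' kept in the file's native voxel grid; the NIfTI `scl_slope`/`scl_inter`
#' scaling is applied (as the format requires), but qform/sform orientation is
#' only used to label axes, never to resample. Trailing singleton dimensions
#' (e.g. a 4th dimension of length 1) are dropped.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [tex_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  # squeeze trailing singleton dims
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) < 3L)
    stop("volume must have at least 3 spatial dimensions, got ", length(d))
  if (length(d) > 3L)
    stop("volume has ", length(d), " non-singleton dimensions; expected 3")
  arr <- array(as.numeric(img), dim = d)
  # pixdim is stored as float32; round away the representation noise
  spacing <- signif(RNifti::pixdim(img)[1:3], 7)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  labels <- orientation_to_labels(tryCatch(RNifti::orientation(img),
                                           error = function(e) NULL))
  tex_volume(arr, spacing = spacing, axis_labels = labels)
}

#' Write a volume to NIfTI
#'
#' @param volume a [tex_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "tex_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Names of the 25 texture features
#'
#' The feature panel, in canonical column order: 3 global intensity-histogram
#' features, 9 GLCM features and 13 GLRLM features.
#'
#' @return Character vector of length 25.
#' @export
feature_names <- function() {
  c("Global Variance", "Skewness", "Kurtosis",
    "Energy", "Contrast", "Entropy", "Homogeneity", "Correlation",
    "Sum Average", "Variance", "Dissimilarity", "Autocorrelation",
    "SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
    "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")
}

table_meta_cols <- function() {
  c("subject_id", "group", "roi_id", "side", "shape", "radius_vox")
}

validate_feature_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) < 1L)
    stop("feature table must be a non-empty data frame")
  need <- c(table_meta_cols(), feature_names())
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(table), need)
  if (length(extra))
    stop("feature table has unknown columns: ", paste(extra, collapse = ", "))
  table[, need, drop = FALSE]
}

#' Write a feature table to CSV
#'
#' One row per (subject, ROI); columns are `subject_id`, `group`, `roi_id`,
#' `side`, `shape`, `radius_vox` followed by the 25 feature names from
#' [feature_names()]. Missing (undefined) feature values are serialized as
#' `NA`.
#'
#' @param table data frame as produced by [extract_features()] row-binding.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return A data frame with the canonical feature-table columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop("cannot read feature table: file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  tab <- validate_feature_table(tab)
  for (fn in feature_names()) tab[[fn]] <- as.numeric(tab[[fn]])
  tab
}
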