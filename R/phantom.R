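#' Phantom cohort specification
#'
#' Describes a synthetic three-group cohort of volumes whose designated
#' "hippocampal" regions differ in local texture. Each volume is
#' `mean_intensity + gradient * (axis-1 index) + noise`, where the noise is
#' Gaussian white noise of standard deviation `noise_sd`, optionally
#' convolved with a Gaussian kernel of full width at half maximum
#' `smooth_fwhm_vox` voxels. Smoothing injects spatial autocorrelation — the
#' texture knob: its effect on co-occurrence features (Correlation up,
#' Contrast down) is analytically predictable, which is what makes the
#' phantoms usable as ground truth. Phantoms are abstract noise blocks, not
#' anatomically realistic brains: the pipeline consumes intensities under
#' masks, so anatomy is irrelevant to its correctness.
#'
#' The defaults emulate the three-group hippocampal study design: 35
#' subjects per group (CN, EMCI, AD), two seed points ("left"/"right") that
#' admit radius-8 spheres, identical CN and EMCI texture, and a smoothed
#' (FWHM 2 voxels) AD texture — so AD differs from both CN and EMCI while
#' CN and EMCI are exchangeable.
#'
#' @param n_per_group subjects per group, >= 2 (default 35).
#' @param vol_shape integer length-3 volume dimensions (default 40^3).
#' @param centers named list of two 1-based integer seed points, names used
#'   as the `side` labels (default `left`, `right`).
#' @param group_params named list (one entry per group) of lists with
#'   `noise_sd`, `smooth_fwhm_vox`, `mean_intensity`, `gradient`.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_per_group = 35L,
                         vol_shape = c(40L, 40L, 40L),
                         centers = list(left = c(13L, 20L, 20L),
                                        right = c(28L, 20L, 20L)),
                         group_params = list(
                           CN = list(noise_sd = 10, smooth_fwhm_vox = 0,
                                     mean_intensity = 100, gradient = 0),
                           EMCI = list(noise_sd = 10, smooth_fwhm_vox = 0,
                                       mean_intensity = 100, gradient = 0),
                           AD = list(noise_sd = 10, smooth_fwhm_vox = 2,
                                     mean_intensity = 100, gradient = 0)),
                         seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L)
    stop("'n_per_group' must be an integer >= 2")
  vol_shape <- as.integer(vol_shape)
  if (length(vol_shape) != 3L || any(vol_shape < 1L))
    stop("'vol_shape' must be 3 positive integers")
  if (!is.list(centers) || length(centers) < 1L || is.null(names(centers)))
    stop("'centers' must be a named list of seed points")
  for (ctr in centers) {
    ctr <- as.integer(ctr)
    if (length(ctr) != 3L || any(ctr - 8L < 1L) || any(ctr + 8L > vol_shape))
      stop("each center must admit a radius-8 sphere inside vol_shape")
  }
  if (!is.list(group_params) || length(group_params) < 2L ||
      is.null(names(group_params)))
    stop("'group_params' must be a named list with one entry per group")
  for (gp in group_params) {
    need <- c("noise_sd", "smooth_fwhm_vox", "mean_intensity", "gradient")
    if (!all(need %in% names(gp)))
      stop("each group's params need: ", paste(need, collapse = ", "))
    if (gp$noise_sd <= 0) stop("'noise_sd' must be positive")
    if (gp$smooth_fwhm_vox < 0) stop("'smooth_fwhm_vox' must be >= 0")
  }
  structure(list(n_per_group = n_per_group, vol_shape = vol_shape,
                 centers = lapply(centers, as.integer),
                 group_params = group_params, seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian convolution by shift-and-add, zero padding; the kernel
# is truncated at 3 standard deviations and normalized to sum 1 per axis
gaussian_smooth <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-rad:rad, sd = sd)
  k <- k / sum(k)
  dims <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, dim = dims)
    n <- dims[axis]
    for (t in -rad:rad) {
      lo <- max(1L, 1L + t); hi <- min(n, n + t)
      if (lo > hi) next  # shift exceeds the axis extent
      src <- seq.int(lo, hi)
      dst <- src - t
      si <- di <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
      si[[axis]] <- src; di[[axis]] <- dst
      out[di[[1]], di[[2]], di[[3]]] <- out[di[[1]], di[[2]], di[[3]]] +
        k[t + rad + 1L] * arr[si[[1]], si[[2]], si[[3]]]
    }
    arr <- out
  }
  arr
}

# one phantom volume; RNG state must be set by the caller
phantom_volume <- function(vol_shape, params) {
  noise <- array(stats::rnorm(prod(vol_shape), sd = params$noise_sd),
                 dim = vol_shape)
  noise <- gaussian_smooth(noise, params$smooth_fwhm_vox)
  ramp <- array(rep((seq_len(vol_shape[1]) - 1) * params$gradient,
                    times = prod(vol_shape[2:3])), dim = vol_shape)
  tex_volume(params$mean_intensity + ramp + noise)
}

#' Generate a synthetic phantom cohort
#'
#' Produces one volume per subject, deterministic given `spec$seed`: a
#' per-subject sub-seed stream is drawn once from the spec seed (Mersenne-
#' Twister throughout), so any subject's volume is reproducible
#' independently of the others. Re-running with the same spec yields
#' bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir if non-NULL, write `<subject_id>.nii.gz` volumes plus
#'   `centers.csv` (subject_id, side, x, y, z — 1-based voxel indices),
#'   `groups.csv` (subject_id, group) and a `manifest.yaml` there.
#' @return Invisibly for `out_dir` runs, otherwise visibly: a list with
#'   `subjects` (data.frame subject_id, group), `volumes` (named list of
#'   [tex_volume()]), `centers` (data.frame subject_id, side, x, y, z) and
#'   `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  groups <- names(spec$group_params)
  n_total <- spec$n_per_group * length(groups)
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  subject_id <- character(n_total)
  group <- character(n_total)
  volumes <- vector("list", n_total)
  idx <- 0L
  for (g in groups) {
    for (i in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      subject_id[idx] <- sprintf("%s%03d", g, i)
      group[idx] <- g
      set.seed(sub_seeds[idx])
      volumes[[idx]] <- phantom_volume(spec$vol_shape,
                                       spec$group_params[[g]])
    }
  }
  names(volumes) <- subject_id
  subjects <- data.frame(subject_id = subject_id, group = group,
                         stringsAsFactors = FALSE)
  centers <- do.call(rbind, lapply(subject_id, function(sid) {
    do.call(rbind, lapply(names(spec$centers), function(side) {
      ctr <- spec$centers[[side]]
      data.frame(subject_id = sid, side = side,
                 x = ctr[1], y = ctr[2], z = ctr[3],
                 stringsAsFactors = FALSE)
    }))
  }))

  out <- list(subjects = subjects, volumes = volumes, centers = centers,
              spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in subject_id)
      write_volume(volumes[[sid]], file.path(out_dir,
                                             paste0(sid, ".nii.gz")))
    utils::write.csv(centers, file.path(out_dir, "centers.csv"),
                     row.names = FALSE)
    utils::write.csv(subjects, file.path(out_dir, "groups.csv"),
                     row.names = FALSE)
    manifest <- list(
      n_per_group = spec$n_per_group,
      vol_shape = as.integer(spec$vol_shape),
      groups = groups,
      seed = spec$seed,
      n_volumes = n_total,
      files = paste0(subject_id, ".nii.gz"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    return(invisible(out))
  }
  out
}

#' Bundled worked example: one smoothed-noise phantom and its feature panel
#'
#' Builds a 32x32x32 phantom (Gaussian noise, FWHM 1.5 voxel smoothing,
#' fixed internal seed), places radius-5 circular and spherical ROIs at its
#' center, and extracts the 25-feature panel for both. The expected values
#' shipped in `inst/extdata/worked_example_features.csv` were computed by
#' this implementation once and frozen; they serve as a regression pin and
#' as the numbers quoted in the documentation.
#'
#' @param out_dir if non-NULL, write the phantom volume and its centers CSV
#'   there.
#' @return List with `volume`, `masks` (circle and sphere), `features`
#'   (data.frame: feature, circle2d, sphere3d) and `expected` (the bundled
#'   frozen values, same shape).
#' @export
worked_example <- function(out_dir = NULL) {
  seed <- 20180L
  shape <- c(32L, 32L, 32L)
  center <- c(16L, 16L, 16L)
  params <- list(noise_sd = 10, smooth_fwhm_vox = 1.5,
                 mean_intensity = 100, gradient = 0)
  set.seed(seed)
  vol <- phantom_volume(shape, params)
  circ <- circular_mask(shape, center, 5)
  sph <- spherical_mask(shape, center, 5)
  features <- data.frame(
    feature = feature_names(),
    circle2d = unname(extract_features(vol, circ)),
    sphere3d = unname(extract_features(vol, sph)),
    stringsAsFactors = FALSE)
  expected_path <- system.file("extdata", "worked_example_features.csv",
                               package = "roitexture")
  expected <- if (nzchar(expected_path))
    utils::read.csv(expected_path, stringsAsFactors = FALSE) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(vol, file.path(out_dir, "worked_example.nii.gz"))
    utils::write.csv(data.frame(subject_id = "example", side = "left",
                                x = center[1], y = center[2], z = center[3]),
                     file.path(out_dir, "centers.csv"), row.names = FALSE)
  }
  list(volume = vol, masks = list(circle = circ, sphere = sph),
       features = features, expected = expected)
}
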