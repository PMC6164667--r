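# small constructors for hand-built matrix fixtures
qroi_from_levels <- function(lv, ng) {
  quantized_roi(lv, !is.na(lv), ng)
}
dirset <- function(offsets, weights = rep(1 / length(offsets),
                                          length(offsets))) {
  structure(list(offsets = lapply(offsets, as.integer), weights = weights),
            class = "direction_set")
}

test_that("direction sets have the contracted structure", {
  d2 <- directions("2d", slice_axis = 2)
  expect_length(d2$offsets, 4)
  expect_equal(d2$weights, rep(0.25, 4))
  expect_true(all(vapply(d2$offsets, function(d) d[2] == 0L, logical(1))))

  d3 <- directions("3d")
  expect_length(d3$offsets, 13)
  lens <- vapply(d3$offsets, function(d) sqrt(sum(d^2)), numeric(1))
  expect_equal(sum(lens == 1), 3)          # axis steps
  expect_equal(sum(abs(lens - sqrt(2)) < 1e-12), 6)  # face diagonals
  expect_equal(sum(abs(lens - sqrt(3)) < 1e-12), 4)  # space diagonals
  expect_equal(sum(d3$weights), 1, tolerance = 1e-12)
  # inverse-length weighting: axis : face : space = 1 : 1/sqrt(2) : 1/sqrt(3)
  w_axis <- d3$weights[abs(lens - 1) < 1e-12][1]
  w_face <- d3$weights[abs(lens - sqrt(2)) < 1e-12][1]
  w_space <- d3$weights[abs(lens - sqrt(3)) < 1e-12][1]
  expect_equal(w_face / w_axis, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(w_space / w_axis, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(w_axis, 1 / (3 + 6 / sqrt(2) + 4 / sqrt(3)), tolerance = 1e-12)
  # no offset is the negation of another
  for (i in seq_along(d3$offsets)) for (j in seq_along(d3$offsets))
    if (i != j) expect_false(all(d3$offsets[[i]] == -d3$offsets[[j]]))
})

test_that("glcm matches hand-enumerated pair counts", {
  # single pair [1, 2] along one offset: symmetrized halves
  q <- qroi_from_levels(array(c(1L, 2L), c(1, 2, 1)), 2)
  g <- glcm(q, dirset(list(c(0, 1, 0))))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # constant 4x4 ROI at one level concentrates all mass on the diagonal
  qc <- qroi_from_levels(array(5L, c(4, 4, 1)), 8)
  gc <- glcm(qc, directions("2d", slice_axis = 3))
  expect_equal(gc$p[5, 5], 1)
  expect_equal(sum(gc$p), 1)

  # 3x3 checkerboard with the two axis offsets: only cross-level pairs
  lv <- array(NA_integer_, c(3, 3, 1))
  lv[, , 1] <- (outer(1:3, 1:3, "+") %% 2L) + 1L
  gb <- glcm(qroi_from_levels(lv, 2),
             dirset(list(c(0, 1, 0), c(1, 0, 0))))
  expect_equal(gb$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("glcm is symmetric, normalized, and hole pairs are excluded", {
  set.seed(21)
  for (i in 1:10) {
    lv <- random_quantized_grid(c(5, 5, 5), ng = 4)
    g <- glcm(qroi_from_levels(lv, 4), directions("3d"))
    expect_equal(g$p, t(g$p))
    expect_equal(sum(g$p), 1, tolerance = 1e-9)
    expect_true(all(g$p >= 0))
  }
  # a lone valid cell has no pairs in any direction
  lv1 <- array(NA_integer_, c(3, 3, 3)); lv1[2, 2, 2] <- 1L
  expect_error(glcm(qroi_from_levels(lv1, 2), directions("3d")),
               "degenerate")
})

test_that("glcm features reproduce closed-form hand computations", {
  # single-entry matrix at level 5
  p5 <- matrix(0, 8, 8); p5[5, 5] <- 1
  f <- glcm_features(structure(list(p = p5, n_levels = 8), class = "glcm"))
  expect_equal(f[["Energy"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Homogeneity"]], 1)
  expect_true(is.na(f[["Correlation"]]))
  expect_equal(f[["Sum Average"]], 10)
  expect_equal(f[["Variance"]], 0)
  expect_equal(f[["Dissimilarity"]], 0)
  expect_equal(f[["Autocorrelation"]], 25)

  # checkerboard matrix: mu = 1.5, sigma^2 = 0.25
  pc <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  fc <- glcm_features(structure(list(p = pc, n_levels = 2), class = "glcm"))
  expect_equal(fc[["Contrast"]], 1)
  expect_equal(fc[["Correlation"]], -1)
  expect_equal(fc[["Energy"]], 0.5)
  expect_equal(fc[["Entropy"]], 1)
  expect_equal(fc[["Homogeneity"]], 0.5)
  expect_equal(fc[["Autocorrelation"]], 2)
  expect_equal(fc[["Sum Average"]], 3)
})

test_that("glcm features equal an independent brute-force evaluator", {
  set.seed(22)
  for (i in 1:20) {
    ng <- sample(2:6, 1)
    raw <- matrix(rexp(ng * ng), ng, ng)
    p <- (raw + t(raw)) / (2 * sum(raw))
    f <- glcm_features(structure(list(p = p, n_levels = ng), class = "glcm"))
    o <- oracle_glcm_features(p)
    expect_equal(unname(f), unname(o), tolerance = 1e-12)
  }
})

test_that("glrlm matches hand-scanned runs", {
  # row [1, 1, 1]: one run of length 3
  q <- qroi_from_levels(array(1L, c(1, 3, 1)), 2)
  g <- glrlm(q, dirset(list(c(0, 1, 0))))
  expect_equal(g$r[1, 3], 1)
  expect_equal(g$n_runs, 1)
  expect_equal(g$n_voxels, 3L)

  # row [1, 2, 2]: runs (1, len 1) and (2, len 2)
  q2 <- qroi_from_levels(array(c(1L, 2L, 2L), c(1, 3, 1)), 2)
  g2 <- glrlm(q2, dirset(list(c(0, 1, 0))))
  expect_equal(g2$r[1, 1], 1)
  expect_equal(g2$r[2, 2], 1)
  expect_equal(g2$n_runs, 2)

  # constant n-cube along one axis: n^(dim-1) runs of length n
  for (n in c(3, 4)) {
    qc <- qroi_from_levels(array(2L, c(n, n, n)), 3)
    gc <- glrlm(qc, dirset(list(c(1, 0, 0))))
    expect_equal(gc$r[2, n], n^2)
    expect_equal(sum(gc$r), n^2)
  }

  # runs break at holes: [1, NA, 1] is two runs of length 1
  qh <- qroi_from_levels(array(c(1L, NA, 1L), c(1, 3, 1)), 2)
  gh <- glrlm(qh, dirset(list(c(0, 1, 0))))
  expect_equal(gh$r[1, 1], 2)
})

test_that("glrlm features reproduce closed-form hand computations", {
  g1 <- structure(list(r = {
    r <- matrix(0, 2, 3); r[1, 3] <- 1; r
  }, n_runs = 1, n_voxels = 3L, n_levels = 2), class = "glrlm")
  f1 <- glrlm_features(g1)
  expect_equal(unname(f1), c(1 / 9, 9, 1, 1, 1 / 3, 1, 1, 1 / 9, 1 / 9,
                             9, 9, 0, 0))

  g2 <- structure(list(r = {
    r <- matrix(0, 2, 3); r[1, 1] <- 1; r[2, 2] <- 1; r
  }, n_runs = 2, n_voxels = 3L, n_levels = 2), class = "glrlm")
  f2 <- glrlm_features(g2)
  expect_equal(f2[["SRE"]], 0.625)
  expect_equal(f2[["RP"]], 2 / 3)
  expect_equal(f2[["GLV"]], 0.25)
  expect_equal(f2[["RLV"]], 0.25)

  # no two equal neighbours in any of the 4 directions (levels step by
  # +1, +2, +3, -1 mod 4 along the four offsets): every run has length 1
  lv <- array(NA_integer_, c(4, 4, 1))
  lv[, , 1] <- ((outer(1:4, 2L * (1:4), "+")) %% 4L) + 1L
  ga <- glrlm(qroi_from_levels(lv, 4), directions("2d", slice_axis = 3))
  fa <- glrlm_features(ga)
  expect_equal(fa[["SRE"]], 1)
  expect_equal(fa[["LRE"]], 1)
  expect_equal(fa[["RP"]], 1)
})

test_that("histogram features match hand-computed central moments", {
  qc <- qroi_from_levels(array(1L, c(2, 2, 1)), 4)
  fc <- histogram_features(qc)
  expect_equal(fc[["Global Variance"]], 0)
  expect_true(is.na(fc[["Skewness"]]))
  expect_true(is.na(fc[["Kurtosis"]]))

  q <- qroi_from_levels(array(c(1L, 2L, 2L, 3L), c(4, 1, 1)), 4)
  f <- histogram_features(q)
  expect_equal(f[["Global Variance"]], 0.5)
  expect_equal(f[["Skewness"]], 0)
  expect_equal(f[["Kurtosis"]], 2)
})

test_that("histogram moments of uniform levels approach closed forms", {
  set.seed(23)
  lv <- array(sample.int(64L, 2e5, replace = TRUE), c(2e5, 1, 1))
  f <- histogram_features(qroi_from_levels(lv, 64))
  expect_lt(abs(f[["Skewness"]]), 0.05)
  expect_lt(abs(f[["Kurtosis"]] - 1.8), 0.05)  # discrete-uniform kurtosis
})

test_that("extract_features returns the 25-feature panel", {
  set.seed(24)
  vol <- tex_volume(array(rnorm(17^3, 100, 10), dim = c(17, 17, 17)))
  sph <- spherical_mask(c(17, 17, 17), c(9, 9, 9), 3)
  circ <- circular_mask(c(17, 17, 17), c(9, 9, 9), 3)
  fs <- extract_features(vol, sph)
  fc <- extract_features(vol, circ)
  expect_identical(names(fs), feature_names())
  expect_identical(names(fc), feature_names())
  expect_true(all(!is.na(fs)))
  # sphere and circle at another radius still give full panels
  f5 <- extract_features(vol, spherical_mask(c(17, 17, 17), c(9, 9, 9), 5))
  expect_true(all(!is.na(f5)))
  expect_false(all(f5 == fs))
  # built-in range invariants
  expect_gt(fs[["Energy"]], 0); expect_lte(fs[["Energy"]], 1)
  expect_gte(fs[["Entropy"]], 0)
  expect_gte(fs[["LRE"]], 1)
  expect_true(fs[["SRE"]] > 0 && fs[["SRE"]] <= 1)
  expect_true(fs[["RP"]] > 0 && fs[["RP"]] <= 1)
})

test_that("features are invariant to affine intensity rescaling end-to-end", {
  set.seed(25)
  arr <- array(rnorm(13^3, 50, 5), dim = c(13, 13, 13))
  mask <- spherical_mask(c(13, 13, 13), c(7, 7, 7), 4)
  f1 <- extract_features(tex_volume(arr), mask)
  f2 <- extract_features(tex_volume(2.5 * arr + 1000), mask)
  expect_equal(f1, f2, tolerance = 1e-12)
})
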