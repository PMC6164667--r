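# Independent brute-force oracles, deliberately written with naive loops and
# kept free of any package internals so they can arbitrate correctness.

# number of integer lattice points (i, j) with i^2 + j^2 <= r^2
oracle_disc_count <- function(r) {
  n <- 0L
  for (i in -ceiling(r):ceiling(r))
    for (j in -ceiling(r):ceiling(r))
      if (i^2 + j^2 <= r^2) n <- n + 1L
  n
}

oracle_ball_count <- function(r) {
  n <- 0L
  for (i in -ceiling(r):ceiling(r))
    for (j in -ceiling(r):ceiling(r))
      for (k in -ceiling(r):ceiling(r))
        if (i^2 + j^2 + k^2 <= r^2) n <- n + 1L
  n
}

# brute-force symmetric co-occurrence probability matrix: lv is an integer
# array with NA at invalid cells; offsets a list of integer 3-vectors
oracle_glcm <- function(lv, offsets, weights, ng) {
  dims <- dim(lv)
  p <- matrix(0, ng, ng)
  wsum <- 0
  for (k in seq_along(offsets)) {
    d <- offsets[[k]]
    counts <- matrix(0, ng, ng)
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (l in seq_len(dims[3])) {
        ii <- i + d[1]; jj <- j + d[2]; ll <- l + d[3]
        if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
            ll < 1 || ll > dims[3]) next
        a <- lv[i, j, l]; b <- lv[ii, jj, ll]
        if (is.na(a) || is.na(b)) next
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    if (sum(counts) > 0) {
      p <- p + weights[k] * counts / sum(counts)
      wsum <- wsum + weights[k]
    }
  }
  if (wsum == 0) stop("no pairs")
  p / wsum
}

# brute-force run-length matrix: walk every line in each direction
oracle_glrlm <- function(lv, offsets, weights, ng, lmax) {
  dims <- dim(lv)
  inside <- function(c3) all(c3 >= 1) && all(c3 <= dims)
  r <- matrix(0, ng, lmax)
  for (k in seq_along(offsets)) {
    d <- offsets[[k]]
    rd <- matrix(0, ng, lmax)
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (l in seq_len(dims[3])) {
        c0 <- c(i, j, l)
        if (is.na(lv[i, j, l])) next
        prev <- c0 - d
        # run starts here iff predecessor is outside, invalid, or different
        if (inside(prev) && !is.na(lv[prev[1], prev[2], prev[3]]) &&
            lv[prev[1], prev[2], prev[3]] == lv[i, j, l]) next
        len <- 1L
        nxt <- c0 + d
        while (inside(nxt) && !is.na(lv[nxt[1], nxt[2], nxt[3]]) &&
               lv[nxt[1], nxt[2], nxt[3]] == lv[i, j, l]) {
          len <- len + 1L
          nxt <- nxt + d
        }
        rd[lv[i, j, l], len] <- rd[lv[i, j, l], len] + 1
      }
    r <- r + weights[k] * rd
  }
  r
}

# brute-force GLCM feature panel, looping over all (i, j)
oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  s2 <- sum((seq_len(ng) - mu)^2 * px)
  energy <- contrast <- entropy <- homog <- ij <- sumavg <- vari <- dis <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    v <- p[i, j]
    energy <- energy + v^2
    contrast <- contrast + (i - j)^2 * v
    if (v > 0) entropy <- entropy - v * log2(v)
    homog <- homog + v / (1 + abs(i - j))
    ij <- ij + i * j * v
    sumavg <- sumavg + (i + j) * v
    vari <- vari + (i - mu)^2 * v
    dis <- dis + abs(i - j) * v
  }
  c(Energy = energy, Contrast = contrast, Entropy = entropy,
    Homogeneity = homog,
    Correlation = if (s2 > 0) (ij - mu^2) / s2 else NA_real_,
    `Sum Average` = sumavg, Variance = vari, Dissimilarity = dis,
    Autocorrelation = ij)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mww_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">"))  # tie-free inputs assumed
  }
  u_obs <- sum(outer(x, y, ">"))
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, u_of)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# hand step-up Benjamini-Hochberg adjustment
oracle_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, m * ps[k] / k)
    adj[k] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# random quantized grid with NA holes, as a quantized_roi plus raw levels
random_quantized_grid <- function(dims, ng, p_hole = 0.15) {
  lv <- array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
  holes <- array(stats::runif(prod(dims)) < p_hole, dim = dims)
  if (all(holes)) holes[1] <- FALSE
  lv[holes] <- NA_integer_
  lv
}

# minimal valid feature table with supplied generator for feature values
make_feature_table <- function(n_per_group, groups = c("AD", "CN", "EMCI"),
                               roi_ids = "ROI1_left_2D",
                               gen = function(group, feature, n) stats::rnorm(n)) {
  rows <- list()
  for (roi in roi_ids) for (g in groups) {
    block <- data.frame(
      subject_id = sprintf("%s%03d", g, seq_len(n_per_group)),
      group = g, roi_id = roi, side = "left", shape = "circle2d",
      radius_vox = 3, stringsAsFactors = FALSE)
    for (fn in feature_names()) block[[fn]] <- gen(g, fn, n_per_group)
    rows[[length(rows) + 1L]] <- block
  }
  do.call(rbind, rows)
}

# write a minimal NIfTI-1 file with int16 data and given scl slope/intercept,
# so scaling behaviour can be checked against a file the package did not write
write_scaled_nifti <- function(path, values_int16, dims, slope, inter) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  writeBin(as.integer(c(3, dims, 1, 1, 1, 1)), con, size = 2)
  writeBin(raw(14), con)
  writeBin(4L, con, size = 2)    # datatype int16
  writeBin(16L, con, size = 2)   # bitpix
  writeBin(0L, con, size = 2)
  writeBin(c(1, 1, 1, 1, 0, 0, 0, 0), con, size = 4)  # pixdim
  writeBin(352, con, size = 4)   # vox_offset
  writeBin(slope, con, size = 4)
  writeBin(inter, con, size = 4)
  writeBin(raw(68), con)
  seek(con, 344)
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(as.raw(0), con)
  seek(con, 348)
  writeBin(raw(4), con)
  writeBin(as.integer(values_int16), con, size = 2)
}
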