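# Shared fixtures and independent oracles. Oracles are deliberately written
# as brute-force enumerations, independent of the package's implementation
# paths they check.

# Digital ball of radius r centered at `center` (1-based voxel indices).
make_ball <- function(dims, center, r) {
  a <- array(0L, dims)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  a[idx[d2 <= r^2, , drop = FALSE]] <- 1L
  a
}

# The overlapping two-sphere instance-separation fixture: radius 6, centers
# 10 voxels apart.
two_sphere_fixture <- function() {
  dims <- c(24, 34, 24)
  a <- make_ball(dims, c(12, 12, 12), 6)
  b <- make_ball(dims, c(12, 22, 12), 6)
  mask <- array(as.integer(a | b), dims)
  list(mask = mask, centers = list(c(12, 12, 12), c(12, 22, 12)),
       dims = dims)
}

# Oracle: number of 1D covering windows of length `tile` with >= `overlap`
# shared voxels, by direct enumeration of the placement rule.
oracle_cover_count_1d <- function(n, tile, overlap) {
  step <- tile - overlap
  starts <- 0
  while (tail(starts, 1) + tile < n) {
    nxt <- tail(starts, 1) + step
    if (nxt + tile > n) nxt <- n - tile
    starts <- c(starts, nxt)
  }
  length(starts)
}

# Oracle: voxel confusion counts by an explicit per-voxel loop.
oracle_voxel_counts <- function(T, S) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(T)) {
    if (T[i] > 0 && S[i] > 0) tp <- tp + 1L
    else if (T[i] == 0 && S[i] == 0) tn <- tn + 1L
    else if (T[i] == 0 && S[i] > 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Oracle: Otsu split by brute-force evaluation of the between-class variance
# directly from the data values, for every candidate split of the binned
# range.
oracle_otsu_split <- function(v, n_bins) {
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    lo <- bin <= t
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- mean(mids[bin[lo]]); mu1 <- mean(mids[bin[!lo]])
    sb2 <- w0 * w1 * (mu0 - mu1)^2
    if (sb2 > best + 1e-12) { best <- sb2; best_t <- t }
  }
  list(split = best_t, threshold = edges[best_t + 1])
}

# Oracle: rasterized voxel set of an ellipsoid by exhaustively scanning every
# voxel center of the grid against the quadratic form.
oracle_ellipsoid_voxels <- function(center, semi_axes, rotation, dims) {
  Rz <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  Ry <- function(b) matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
                           3, 3, byrow = TRUE)
  Rx <- function(g) matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  R <- Rz(rotation[1]) %*% Ry(rotation[2]) %*% Rx(rotation[3])
  out <- NULL
  for (x in 0:(dims[3] - 1)) for (y in 0:(dims[2] - 1))
    for (z in 0:(dims[1] - 1)) {
      d <- c(z, y, x) - center
      b <- as.vector(t(R) %*% d)
      if (sum((b / semi_axes)^2) <= 1) out <- rbind(out, c(z, y, x))
    }
  out
}

# Tiny renderer settings used across tests (deterministic unless stated).
quiet_render_config <- function(seed = 1L, ...) {
  render_config(psf_sigma = c(0, 0, 0), vignetting_strength = 0,
                depth_decay = 0, intensity_jitter = 0, noise_sd = 0,
                seed = seed, ...)
}
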