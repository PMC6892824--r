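#' @title Synthetic ellipsoid phantom generation
#' @name synthetic_masks
#' @description Generate binary/labeled 3D volumes of ellipsoidal "nuclei"
#'   with random rotations and translations, under a cap on the pairwise
#'   voxel overlap between any two nuclei. These phantoms serve as ground
#'   truth for training the segmenter without manual annotation.
NULL

#' Ellipsoid specification
#'
#' @param center numeric (z, y, x) center in voxel coordinates (0-based,
#'   continuous; voxel centers sit at integer coordinates).
#' @param semi_axes numeric (a, b, c) semi-axis lengths in voxels, all > 0.
#' @param rotation numeric Euler angles (rad), intrinsic z-y-x convention.
#' @return an `ellipsoid_spec` object.
#' @export
ellipsoid_spec <- function(center, semi_axes, rotation = c(0, 0, 0)) {
  if (any(semi_axes <= 0)) stop("semi-axes must be > 0, got ", min(semi_axes))
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation)),
            class = "ellipsoid_spec")
}

# Rotation matrix from Euler angles (intrinsic rotations about z, then y,
# then x of the (z, y, x) coordinate frame).
euler_rotation_matrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rz <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b),
                 0, 1, 0,
                 -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(cos(g), -sin(g), 0,
                 sin(g), cos(g), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Rasterize an ellipsoid onto a voxel grid
#'
#' A voxel with (0-based) center x is inside iff
#' \eqn{\|D^{-1} R^T (x - c)\|^2 \le 1} with R the rotation matrix and
#' D = diag(semi_axes). The result is clipped to the volume bounds.
#'
#' @param spec an [ellipsoid_spec()].
#' @param volume_shape integer (z, y, x) grid size.
#' @return integer matrix with columns (z, y, x) of 0-based voxel coordinates.
#' @export
rasterize_ellipsoid <- function(spec, volume_shape) {
  if (any(spec$semi_axes <= 0)) stop("degenerate semi-axis")
  R <- euler_rotation_matrix(spec$rotation)
  r_max <- max(spec$semi_axes)
  lo <- pmax(0, floor(spec$center - r_max))
  hi <- pmin(volume_shape - 1, ceiling(spec$center + r_max))
  if (any(lo > hi)) return(matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("z", "y", "x"))))
  g <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3],
                   KEEP.OUT.ATTRS = FALSE)
  d <- t(t(as.matrix(g)) - spec$center)      # n x 3 displacements
  body <- d %*% R                            # = R^T (x - c) rowwise
  q <- (body[, 1] / spec$semi_axes[1])^2 +
       (body[, 2] / spec$semi_axes[2])^2 +
       (body[, 3] / spec$semi_axes[3])^2
  m <- as.matrix(g[q <= 1, , drop = FALSE])
  dimnames(m) <- list(NULL, c("z", "y", "x"))
  storage.mode(m) <- "integer"
  m
}

#' Configuration for phantom mask generation
#'
#' @param volume_shape integer (z, y, x), default 128^3 so that a 2x2x2
#'   subdivision yields eight 64^3 training subvolumes.
#' @param n_nuclei number of ellipsoids to place.
#' @param semi_axis_range (min, max) voxels for every semi-axis, drawn
#'   uniformly; set from the nucleus sizes of the target images.
#' @param max_pairwise_overlap maximum shared voxels allowed between any two
#'   nuclei (default 5).
#' @param max_placement_attempts rejection-sampling budget across the volume.
#' @param seed integer RNG seed.
#' @return a `mask_gen_config` object.
#' @export
mask_gen_config <- function(volume_shape = c(128, 128, 128),
                            n_nuclei = 50,
                            semi_axis_range = c(4, 10),
                            max_pairwise_overlap = 5,
                            max_placement_attempts = 200 * max(n_nuclei, 1),
                            seed = 1L) {
  if (semi_axis_range[1] > semi_axis_range[2])
    stop("semi_axis_range must satisfy min <= max")
  if (max_pairwise_overlap < 0) stop("max_pairwise_overlap must be >= 0")
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  structure(list(volume_shape = as.integer(volume_shape),
                 n_nuclei = as.integer(n_nuclei),
                 semi_axis_range = as.numeric(semi_axis_range),
                 max_pairwise_overlap = as.integer(max_pairwise_overlap),
                 max_placement_attempts = as.integer(max_placement_attempts),
                 seed = as.integer(seed)),
            class = "mask_gen_config")
}

#' Generate one phantom volume of ellipsoidal nuclei
#'
#' Rejection sampling: centers uniform in the volume (ellipsoids may touch
#' the boundary and are clipped), semi-axes uniform in `semi_axis_range`,
#' Euler angles uniform in \[0, 2pi). A placement is rejected if its voxel
#' set shares more than `max_pairwise_overlap` voxels with any earlier
#' nucleus. Contested voxels within the cap belong to the later-placed
#' instance in the label volume; the binary volume is unaffected.
#'
#' @param config a [mask_gen_config()].
#' @return list with `labels` (integer label array), `binary` (0/1 array) and
#'   `specs` (list of [ellipsoid_spec()]). Identical config => identical output.
#' @export
generate_mask_volume <- function(config) {
  stopifnot(inherits(config, "mask_gen_config"))
  vs <- config$volume_shape
  set.seed(config$seed)
  labels <- array(0L, dim = vs)
  specs <- vector("list", config$n_nuclei)
  keys <- vector("list", config$n_nuclei)   # per-instance voxel key sets
  centers <- matrix(0, config$n_nuclei, 3)
  radii <- numeric(config$n_nuclei)
  placed <- 0L
  attempts <- 0L
  while (placed < config$n_nuclei) {
    if (attempts >= config$max_placement_attempts)
      stop("placement budget exhausted: placed ", placed, " of ",
           config$n_nuclei, " nuclei")
    attempts <- attempts + 1L
    sp <- ellipsoid_spec(
      center = runif(3, min = 0, max = vs - 1),
      semi_axes = runif(3, config$semi_axis_range[1], config$semi_axis_range[2]),
      rotation = runif(3, 0, 2 * pi))
    vox <- rasterize_ellipsoid(sp, vs)
    if (nrow(vox) == 0) next
    idx <- vox[, 1] + 1L + vs[1] * (vox[, 2] + vs[2] * vox[, 3])
    # exact pairwise overlap check against each earlier instance's own voxel
    # set (the label map alone would undercount voxels already contested),
    # pre-filtered by bounding spheres
    ok <- TRUE
    if (placed > 0L) {
      r_cand <- max(sp$semi_axes)
      for (i in seq_len(placed)) {
        if (sqrt(sum((centers[i, ] - sp$center)^2)) > radii[i] + r_cand + 2)
          next
        if (sum(idx %in% keys[[i]]) > config$max_pairwise_overlap) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) next
    placed <- placed + 1L
    labels[idx] <- placed
    specs[[placed]] <- sp
    keys[[placed]] <- idx
    centers[placed, ] <- sp$center
    radii[placed] <- max(sp$semi_axes)
  }
  list(labels = labels,
       binary = array(as.integer(labels > 0L), dim = vs),
       specs = specs)
}

#' Pairwise voxel-overlap matrix of a set of ellipsoids
#'
#' Verification utility: entry (i, j) is the size of the intersection of the
#' rasterized voxel sets of ellipsoids i and j. Symmetric, zero diagonal.
#'
#' @param specs list of [ellipsoid_spec()].
#' @param volume_shape integer (z, y, x).
#' @return an n x n integer matrix of intersection voxel counts.
#' @export
pairwise_overlaps <- function(specs, volume_shape) {
  n <- length(specs)
  vs <- as.integer(volume_shape)
  keys <- lapply(specs, function(sp) {
    vox <- rasterize_ellipsoid(sp, vs)
    vox[, 1] + vs[1] * (vox[, 2] + vs[2] * vox[, 3])
  })
  m <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      o <- length(intersect(keys[[i]], keys[[j]]))
      m[i, j] <- o
      m[j, i] <- o
    }
  }
  m
}

#' Generate a dataset of phantom volumes
#'
#' Per-volume seeds are derived deterministically from the master seed so the
#' dataset is reproducible as a whole and per entry.
#'
#' @param config a [mask_gen_config()]; its `seed` acts as the master seed.
#' @param n_volumes number of volumes (>= 1).
#' @return a `mask_dataset`: list with `volumes` (each as from
#'   [generate_mask_volume()]), `config`, `seed`.
#' @export
generate_mask_dataset <- function(config, n_volumes) {
  stopifnot(inherits(config, "mask_gen_config"), n_volumes >= 1)
  vols <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, paste0("mask_volume_", i))
    vols[[i]] <- tryCatch(generate_mask_volume(cfg_i),
                          error = function(e)
                            stop("volume ", i, ": ", conditionMessage(e)))
  }
  structure(list(volumes = vols, config = config, seed = config$seed),
            class = "mask_dataset")
}
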