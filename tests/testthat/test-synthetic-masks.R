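test_that("a sub-voxel ellipsoid on a voxel center rasterizes to that voxel", {
  sp <- ellipsoid_spec(center = c(4, 5, 6), semi_axes = c(0.5, 0.5, 0.5))
  vox <- rasterize_ellipsoid(sp, c(16, 16, 16))
  expect_equal(nrow(vox), 1L)
  expect_equal(as.vector(vox[1, ]), c(4, 5, 6))
  expect_error(rasterize_ellipsoid(
    ellipsoid_spec(c(1, 1, 1), c(1, 1, 1)), c(8, 8, 8)), NA)
  expect_error(ellipsoid_spec(c(1, 1, 1), c(2, 0, 2)), "semi-axes")
})

test_that("rasterization matches the exhaustive quadratic-form oracle", {
  cases <- list(
    list(center = c(7.5, 7.5, 7.5), semi = c(4, 3, 2), rot = c(0, 0, 0)),
    list(center = c(7.0, 8.2, 6.9), semi = c(5, 2.5, 3), rot = c(0.7, -0.3, 1.9)),
    list(center = c(2.0, 13.0, 8.0), semi = c(3, 3, 6), rot = c(2.2, 0.4, 0.1)))
  for (cs in cases) {
    got <- rasterize_ellipsoid(
      ellipsoid_spec(cs$center, cs$semi, cs$rot), c(16, 16, 16))
    want <- oracle_ellipsoid_voxels(cs$center, cs$semi, cs$rot, c(16, 16, 16))
    expect_equal(nrow(got), nrow(want))
    expect_identical(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                     matrix(as.integer(want[order(want[, 1], want[, 2],
                                                  want[, 3]), , drop = FALSE]),
                            ncol = 3, dimnames = list(NULL, c("z", "y", "x"))))
  }
})

test_that("a quarter-turn about z equals the axis-swapped ellipsoid", {
  center <- c(10, 10, 10)
  rot <- rasterize_ellipsoid(
    ellipsoid_spec(center, c(2, 4, 2), rotation = c(pi / 2, 0, 0)), c(21, 21, 21))
  ref <- rasterize_ellipsoid(
    ellipsoid_spec(center, c(2, 2, 4)), c(21, 21, 21))
  ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), ]
  expect_equal(ord(rot), ord(ref))
})

test_that("rasterized volume approaches the continuous ellipsoid volume", {
  semi <- c(9, 8.5, 8)
  vox <- rasterize_ellipsoid(
    ellipsoid_spec(c(15.5, 15.5, 15.5), semi), c(32, 32, 32))
  v_cont <- 4 / 3 * pi * prod(semi)
  expect_lt(abs(nrow(vox) - v_cont) / v_cont, 0.05)
})

test_that("mask generation respects the pairwise overlap cap and determinism", {
  cfg <- mask_gen_config(volume_shape = c(64, 64, 64), n_nuclei = 20,
                         semi_axis_range = c(3, 6), seed = 7)
  mv <- generate_mask_volume(cfg)
  expect_equal(max(mv$labels), 20)
  ov <- pairwise_overlaps(mv$specs, c(64, 64, 64))
  expect_true(isSymmetric(ov))
  expect_true(all(diag(ov) == 0))
  expect_lte(max(ov), cfg$max_pairwise_overlap)
  mv2 <- generate_mask_volume(cfg)
  expect_identical(mv$labels, mv2$labels)
  expect_identical(mv$binary, array(as.integer(mv$labels > 0), dim(mv$labels)))
})

test_that("zero nuclei gives empty volumes; tiny budget raises capacity error", {
  mv <- generate_mask_volume(mask_gen_config(volume_shape = c(8, 8, 8),
                                             n_nuclei = 0, seed = 1))
  expect_true(all(mv$labels == 0))
  expect_length(mv$specs, 0)
  cfg <- mask_gen_config(volume_shape = c(16, 16, 16), n_nuclei = 500,
                         semi_axis_range = c(4, 6),
                         max_placement_attempts = 50, seed = 2)
  expect_error(generate_mask_volume(cfg), "placed")
})

test_that("pairwise_overlaps matches per-pair exhaustive rasterization", {
  set.seed(31)
  dims <- c(20, 20, 20)
  specs <- lapply(1:6, function(i)
    ellipsoid_spec(runif(3, 4, 15), runif(3, 2, 4), runif(3, 0, 2 * pi)))
  got <- pairwise_overlaps(specs, dims)
  keyify <- function(sp) {
    v <- rasterize_ellipsoid(sp, dims)
    paste(v[, 1], v[, 2], v[, 3])
  }
  ks <- lapply(specs, keyify)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(got[i, j], length(intersect(ks[[i]], ks[[j]])),
                 info = paste(i, j))
  # duplicated spec overlaps itself entirely
  dup <- pairwise_overlaps(list(specs[[1]], specs[[1]]), dims)
  expect_equal(dup[1, 2], length(ks[[1]]))
})

test_that("mask datasets are reproducible and satisfy the binary invariant", {
  cfg <- mask_gen_config(volume_shape = c(24, 24, 24), n_nuclei = 4,
                         semi_axis_range = c(2, 4), seed = 9)
  d1 <- generate_mask_dataset(cfg, 3)
  d2 <- generate_mask_dataset(cfg, 3)
  expect_length(d1$volumes, 3)
  for (k in 1:3) {
    expect_identical(d1$volumes[[k]]$labels, d2$volumes[[k]]$labels)
    expect_identical(d1$volumes[[k]]$binary,
                     array(as.integer(d1$volumes[[k]]$labels > 0), c(24, 24, 24)))
  }
  # per-volume seeds differ, so volumes differ
  expect_false(identical(d1$volumes[[1]]$labels, d1$volumes[[2]]$labels))
})
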