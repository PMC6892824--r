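make_phantom <- function(seed = 7, n = 20, dims = c(32, 32, 32)) {
  generate_mask_volume(mask_gen_config(volume_shape = dims, n_nuclei = n,
                                       semi_axis_range = c(2, 4), seed = seed))
}

test_that("the degenerate renderer reproduces the mask exactly", {
  mv <- make_phantom()
  cfg <- quiet_render_config()
  img <- render_volume(mv$labels, cfg)
  want <- cfg$background_level +
    (cfg$foreground_mean - cfg$background_level) * mv$binary
  expect_equal(img, array(want, dim(img)), tolerance = 1e-12)
})

test_that("normalized blur conserves total signal above background", {
  mv <- make_phantom()
  base <- quiet_render_config()
  blurred <- quiet_render_config()
  blurred$psf_sigma <- c(1.5, 1.0, 1.0)
  a <- render_volume(mv$labels, base)
  b <- render_volume(mv$labels, blurred)
  s_a <- sum(a - base$background_level)
  s_b <- sum(b - base$background_level)
  expect_lt(abs(s_a - s_b) / s_a, 1e-6)
})

test_that("foreground stays brighter than background at moderate SNR", {
  mv <- make_phantom()
  cfg <- render_config(seed = 5)  # defaults: SNR ~ 10
  img <- render_volume(mv$labels, cfg)
  expect_gt(mean(img[mv$binary == 1]), mean(img[mv$binary == 0]))
})

test_that("rendering is deterministic under a fixed seed", {
  mv <- make_phantom()
  cfg <- render_config(seed = 21, noise_model = "poisson_gaussian")
  expect_identical(render_volume(mv$labels, cfg), render_volume(mv$labels, cfg))
})

test_that("raising foreground_mean never lowers pre-noise foreground", {
  mv <- make_phantom()
  lo <- quiet_render_config()
  hi <- quiet_render_config()
  hi$foreground_mean <- lo$foreground_mean + 0.1
  a <- render_volume(mv$labels, lo)
  b <- render_volume(mv$labels, hi)
  expect_true(all(b[mv$binary == 1] >= a[mv$binary == 1] - 1e-12))
})

test_that("vignetting darkens slice corners relative to the center", {
  labs <- array(1L, c(8, 33, 33))  # uniform foreground
  cfg <- quiet_render_config()
  cfg$vignetting_strength <- 0.4
  img <- render_volume(labs, cfg)
  sl <- img[4, , ]
  center <- sl[17, 17]
  corners <- mean(c(sl[1, 1], sl[1, 33], sl[33, 1], sl[33, 33]))
  expect_lt(corners, center)
})

test_that("contrast is non-increasing with depth when depth_decay > 0", {
  labs <- array(0L, c(20, 16, 16))
  labs[, 5:12, 5:12] <- 1L  # a foreground column through all slices
  cfg <- quiet_render_config()
  cfg$depth_decay <- 0.02
  img <- render_volume(labs, cfg)
  contrast <- vapply(seq_len(20), function(z)
    mean(img[z, 5:12, 5:12]) - mean(img[z, 1:3, 1:3]), numeric(1))
  expect_true(all(diff(contrast) <= 1e-12))
})

test_that("unpaired pools have matching shapes and reproducible content", {
  ds <- generate_mask_dataset(
    mask_gen_config(volume_shape = c(16, 16, 16), n_nuclei = 3,
                    semi_axis_range = c(2, 3), seed = 4), 4)
  cfg <- render_config(seed = 13)
  p1 <- render_unpaired_pool(ds, cfg, 4)
  p2 <- render_unpaired_pool(ds, cfg, 4)
  expect_length(p1, 4)
  expect_true(all(vapply(p1, function(v) all(dim(v) == c(16, 16, 16)),
                         logical(1))))
  expect_identical(p1, p2)
  expect_error(render_unpaired_pool(ds, cfg, 5), "exceeds")
})

test_that("renderer configuration invariants are enforced", {
  expect_error(render_config(foreground_mean = 0.1, background_level = 0.2),
               "exceed")
  expect_error(render_config(vignetting_strength = 1), "vignetting")
  expect_error(render_config(depth_decay = -0.1), "depth_decay")
})
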