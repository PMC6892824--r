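test_that("dice_loss matches its closed forms", {
  T1 <- c(1, 1, 0, 0)
  expect_equal(dice_loss(T1, T1, eps = 1), 0)          # perfect overlap
  N <- 8
  expect_equal(dice_loss(rep(1, N), rep(0, N), eps = 1), 1 - 1 / (N + 1))
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 0, 0), eps = 1e-12), 1 / 3,
               tolerance = 1e-9)
  expect_error(dice_loss(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("bce_loss matches its closed forms", {
  expect_equal(bce_loss(c(1, 0, 1), rep(0.5, 3)), log(2))
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-6)          # clipping bound
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.2)), -(log(0.9) + log(0.8)) / 2)
})

test_that("combined_loss is the stated linear combination", {
  T0 <- c(1, 1, 0, 0); S0 <- c(0.9, 0.4, 0.2, 0.1)
  d <- dice_loss(T0, S0, 1); b <- bce_loss(T0, S0)
  expect_equal(combined_loss(T0, S0, loss_config(mu1 = 1, mu2 = 0)), d)
  expect_equal(combined_loss(T0, S0, loss_config(mu1 = 0, mu2 = 1)), b)
  expect_equal(combined_loss(T0, S0, loss_config(mu1 = 1, mu2 = 1)), d + b)
  expect_equal(combined_loss(T0, S0, loss_config(mu1 = 2.5, mu2 = 0.5)),
               2.5 * d + 0.5 * b)
  expect_error(loss_config(mu1 = 0, mu2 = 0), "positive")
})

test_that("binarize uses >= and is monotone in the threshold", {
  S <- array(0.7, c(2, 2, 2))
  expect_true(all(binarize(S, 0.5) == 1))
  expect_true(all(binarize(array(0.5, c(2, 2, 2)), 0.5) == 1))  # tie rule
  set.seed(8)
  Sr <- array(runif(5^3), c(5, 5, 5))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t) sum(binarize(Sr, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize(Sr, 0), "threshold")
})

make_training_pairs <- function(n = 8, dims = c(16, 16, 16), seed = 5) {
  ds <- generate_mask_dataset(
    mask_gen_config(volume_shape = dims, n_nuclei = 5,
                    semi_axis_range = c(2, 4), seed = seed), n)
  rc <- render_config(seed = seed + 1)
  lapply(seq_len(n), function(i) {
    rc$seed <- derive_seed(rc$seed, paste0("p", i))
    list(binary = ds$volumes[[i]]$binary,
         intensity = render_volume(ds$volumes[[i]]$labels, rc))
  })
}

test_that("training reduces the combined loss and is seed-reproducible", {
  pairs <- make_training_pairs()
  ucfg <- unet3d_config(levels = 2, base_channels = 2)
  tcfg <- train_config(epochs = 6, batch_size = 1, val_fraction = 0,
                       seed = 11)
  m1 <- train_segmenter(pairs, ucfg, loss_config(), tcfg)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  expect_equal(m1$manifest$learning_rate, 0.001)
  m2 <- train_segmenter(pairs, ucfg, loss_config(), tcfg)
  expect_identical(m1$history, m2$history)
  expect_error(train_segmenter(list(), ucfg), "no training pairs")
})

test_that("tiled prediction preserves shape and is deterministic", {
  pairs <- make_training_pairs(n = 4)
  m <- train_segmenter(pairs, unet3d_config(levels = 2, base_channels = 2),
                       loss_config(),
                       train_config(epochs = 2, batch_size = 2,
                                    val_fraction = 0, seed = 2))
  vol <- array(runif(24^3), c(24, 24, 24))
  p1 <- predict_volume(m, vol, tile_shape = 16, overlap = 8)
  expect_equal(dim(p1), c(24, 24, 24))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict_volume(m, vol, tile_shape = 16, overlap = 8))
})

test_that("a briefly trained model beats the all-background prediction", {
  pairs <- make_training_pairs(n = 9, seed = 23)
  held <- pairs[[9]]
  m <- train_segmenter(pairs[1:8], unet3d_config(levels = 2, base_channels = 4),
                       loss_config(),
                       train_config(epochs = 12, batch_size = 1,
                                    val_fraction = 0, seed = 11))
  pred <- binarize(predict_volume(m, held$intensity), 0.5)
  acc <- mean(pred == held$binary)
  acc_bg <- mean(held$binary == 0)
  expect_gt(acc, acc_bg)
})
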