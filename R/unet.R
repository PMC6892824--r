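#' @title 3D encoder-decoder segmentation network
#' @name segnet
#' @description The binary nucleus segmenter: a U-Net style 3D network with a
#'   down-sampling and an up-sampling path of `levels` resolution levels each.
#'   Every level applies two 3x3x3 convolutions (1-voxel padding, so spatial
#'   size is retained), each followed by normalization and a leaky ReLU;
#'   stride-2 max pooling connects down-path levels, transpose convolutions
#'   up-path levels, and skip concatenation transfers features across. A
#'   final convolution + normalization + sigmoid yields the per-voxel
#'   foreground probability. Trained with Adam on a combined Dice + binary
#'   cross-entropy loss.
NULL

#' U-Net configuration
#'
#' @param levels resolution levels in each path (default 5; input spatial
#'   dims must be divisible by 2^(levels-1)).
#' @param base_channels channels at the first level, doubling per level
#'   (default 64 at paper scale; use small values for CPU-scale runs).
#' @param in_channels input channels (1 for a single nuclear stain).
#' @param leaky_slope negative slope of the leaky ReLU.
#' @return a `unet3d_config` object.
#' @export
unet3d_config <- function(levels = 5, base_channels = 64, in_channels = 1,
                          leaky_slope = 0.01) {
  if (levels < 1) stop("levels must be >= 1")
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 leaky_slope = leaky_slope),
            class = "unet3d_config")
}

# Op list for a U-Net; also used (with levels=2..3) as the GAN generator
# trunk. out_channels/final_sigmoid parameterize the head.
unet_ops <- function(cfg, out_channels = 1, final_sigmoid = TRUE) {
  w <- cfg$base_channels * 2^(seq_len(cfg$levels) - 1)
  ops <- list()
  add <- function(...) ops[[length(ops) + 1]] <<- (...)
  c_prev <- cfg$in_channels
  for (l in seq_len(cfg$levels)) {
    add(nn_conv(c_prev, w[l])); add(nn_bn(w[l])); add(nn_lrelu(cfg$leaky_slope))
    add(nn_conv(w[l], w[l]));   add(nn_bn(w[l])); add(nn_lrelu(cfg$leaky_slope))
    if (l < cfg$levels) { add(nn_save()); add(nn_pool()) }
    c_prev <- w[l]
  }
  if (cfg$levels > 1) {
    for (l in rev(seq_len(cfg$levels - 1))) {
      add(nn_upconv(c_prev, w[l]))
      add(nn_concat())                       # channels: w[l] + w[l]
      add(nn_conv(2 * w[l], w[l])); add(nn_bn(w[l])); add(nn_lrelu(cfg$leaky_slope))
      add(nn_conv(w[l], w[l]));     add(nn_bn(w[l])); add(nn_lrelu(cfg$leaky_slope))
      c_prev <- w[l]
    }
  }
  add(nn_conv(c_prev, out_channels))
  add(nn_bn(out_channels))
  if (final_sigmoid) add(nn_sigmoid())
  ops
}

#' Build the segmentation network
#'
#' Weights are drawn from the current RNG state; call `set.seed()` first for
#' reproducible initialization.
#'
#' @param config a [unet3d_config()].
#' @return a `unet3d_model` (untrained).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "unet3d_config"))
  structure(list(net = list(ops = unet_ops(config)), config = config,
                 history = NULL, manifest = list()),
            class = "unet3d_model")
}

check_divisible <- function(dims, levels) {
  f <- 2^(levels - 1)
  bad <- which(dims %% f != 0)
  if (length(bad))
    stop("input axis ", c("z", "y", "x")[bad[1]], " (", dims[bad[1]],
         ") not divisible by ", f)
  invisible(TRUE)
}

# Forward an intensity array through a unet3d_model; returns list(S, caches).
unet_forward <- function(model, volume) {
  dims <- dim(volume)
  check_divisible(dims, model$config$levels)
  r <- net_forward(model$net, vol_to_feat(volume), as.integer(dims))
  list(S = feat_to_vol(r$out, dims), caches = r$caches, dims = dims)
}

# --- losses -----------------------------------------------------------------

#' Loss configuration for the segmenter
#'
#' @param mu1 weight of the Dice term (>= 0).
#' @param mu2 weight of the binary cross-entropy term (>= 0).
#' @param eps Dice smoothing constant (> 0).
#' @param clip probability clipping distance from 0/1 inside the BCE.
#' @return a `loss_config` object.
#' @export
loss_config <- function(mu1 = 1, mu2 = 1, eps = 1, clip = 1e-7) {
  if (mu1 < 0 || mu2 < 0) stop("loss weights must be >= 0")
  if (mu1 == 0 && mu2 == 0) stop("at least one loss weight must be positive")
  if (eps <= 0) stop("eps must be > 0")
  structure(list(mu1 = mu1, mu2 = mu2, eps = eps, clip = clip),
            class = "loss_config")
}

#' Soft Dice loss
#'
#' `1 - (2*sum(T*S) + eps) / (sum(T) + sum(S) + eps)`: the complement of the
#' smoothed Dice overlap between the binary target and the probability map.
#'
#' @param T binary target array/vector.
#' @param S probability array/vector, same shape.
#' @param eps smoothing constant.
#' @return scalar in \[0, 1).
#' @export
dice_loss <- function(T, S, eps = 1) {
  if (length(T) != length(S)) stop("shape mismatch between T and S")
  1 - (2 * sum(T * S) + eps) / (sum(T) + sum(S) + eps)
}

#' Binary cross-entropy loss (voxel mean)
#'
#' @inheritParams dice_loss
#' @param clip probabilities are clipped to \[clip, 1-clip\].
#' @return scalar >= 0.
#' @export
bce_loss <- function(T, S, clip = 1e-7) {
  if (length(T) != length(S)) stop("shape mismatch between T and S")
  Sc <- pmin(pmax(S, clip), 1 - clip)
  -mean(T * log(Sc) + (1 - T) * log(1 - Sc))
}

#' Combined segmentation loss `mu1 * Dice + mu2 * BCE`
#'
#' @inheritParams dice_loss
#' @param cfg a [loss_config()].
#' @return scalar.
#' @export
combined_loss <- function(T, S, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  cfg$mu1 * dice_loss(T, S, cfg$eps) + cfg$mu2 * bce_loss(T, S, cfg$clip)
}

# Gradient of the combined loss w.r.t. S (same shape as S).
combined_loss_grad <- function(T, S, cfg) {
  g <- 0
  if (cfg$mu1 > 0) {
    D <- sum(T) + sum(S) + cfg$eps
    Num <- 2 * sum(T * S) + cfg$eps
    g <- g + cfg$mu1 * (-(2 * T * D - Num) / D^2)
  }
  if (cfg$mu2 > 0) {
    Sc <- pmin(pmax(S, cfg$clip), 1 - cfg$clip)
    g <- g + cfg$mu2 * ((-T / Sc + (1 - T) / (1 - Sc)) / length(S))
  }
  g
}

# --- training ---------------------------------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size training patches per optimizer step.
#' @param epochs passes over the training pairs.
#' @param val_fraction fraction of pairs held out for validation-based
#'   checkpoint selection (0 disables).
#' @param seed RNG seed for init and shuffling.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 4, epochs = 15,
                         val_fraction = 0.2, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

normalize_intensity <- function(v) {
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
}

#' Train the segmenter on (binary target, intensity) pairs
#'
#' Each pair is a list with `binary` (0/1 array) and `intensity` (array,
#' min-max normalized internally). Adam optimizes the combined Dice+BCE loss;
#' per-epoch train/validation losses are logged and the best-validation
#' parameters are retained in the returned model.
#'
#' @param pairs list of pairs; all spatial dims must be divisible by
#'   2^(levels-1).
#' @param unet_cfg a [unet3d_config()].
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @return a trained `unet3d_model` with `history` (data.frame of epoch,
#'   train_loss, val_loss) and a run `manifest`.
#' @export
train_segmenter <- function(pairs, unet_cfg, loss_cfg = loss_config(),
                            train_cfg = train_config()) {
  if (!length(pairs)) stop("no training pairs supplied")
  set.seed(train_cfg$seed)
  model <- build_network(unet_cfg)
  n <- length(pairs)
  n_val <- floor(train_cfg$val_fraction * n)
  perm <- sample.int(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  xs <- lapply(pairs, function(p) normalize_intensity(p$intensity))
  ts <- lapply(pairs, function(p) p$binary)
  state <- nn_init_adam(model$net)
  t_step <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(loss = Inf, net = model$net)
  eval_loss <- function(net, idx) {
    if (!length(idx)) return(NA_real_)
    mean(vapply(idx, function(i) {
      dims <- dim(xs[[i]])
      check_divisible(dims, unet_cfg$levels)
      S <- net_forward(net, vol_to_feat(xs[[i]]), as.integer(dims))$out
      combined_loss(as.vector(ts[[i]]), as.vector(S), loss_cfg)
    }, numeric(1)))
  }
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = train_cfg$batch_size)) {
      batch <- ord[b0:min(b0 + train_cfg$batch_size - 1, length(ord))]
      acc <- nn_zero_grads(model$net)
      for (i in batch) {
        dims <- dim(xs[[i]])
        check_divisible(dims, unet_cfg$levels)
        fwd <- net_forward(model$net, vol_to_feat(xs[[i]]), as.integer(dims))
        Tv <- as.vector(ts[[i]])
        Sv <- as.vector(fwd$out)
        ep_losses <- c(ep_losses, combined_loss(Tv, Sv, loss_cfg))
        dS <- matrix(combined_loss_grad(Tv, Sv, loss_cfg), nrow = 1)
        acc <- nn_add_grads(acc, net_backward(model$net, fwd$caches, dS)$grads)
      }
      acc <- nn_scale_grads(acc, 1 / length(batch))
      t_step <- t_step + 1
      upd <- nn_adam_step(model$net, acc, state, train_cfg$learning_rate,
                          t = t_step)
      model$net <- upd$net
      state <- upd$state
    }
    vl <- eval_loss(model$net, val_idx)
    sel <- if (is.na(vl)) mean(ep_losses) else vl
    if (sel < best$loss) best <- list(loss = sel, net = model$net)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   val_loss = vl))
  }
  model$net <- best$net
  model$history <- hist
  model$manifest <- list(learning_rate = train_cfg$learning_rate,
                         batch_size = train_cfg$batch_size,
                         epochs = train_cfg$epochs, seed = train_cfg$seed,
                         n_pairs = n, n_validation = n_val,
                         mu1 = loss_cfg$mu1, mu2 = loss_cfg$mu2)
  model
}

#' Predict a foreground probability volume
#'
#' The volume is min-max normalized, tiled if a tile shape is given (or if
#' its dims are not divisible by the network's downsampling factor), pushed
#' through the network, and tile probabilities are stitched with mean
#' blending.
#'
#' @param model a trained `unet3d_model`.
#' @param volume intensity array.
#' @param tile_shape optional (z, y, x) tile size (divisible by
#'   2^(levels-1)); NULL processes the whole volume in one pass.
#' @param overlap tile overlap in voxels (used when tiling).
#' @return probability array in \[0, 1\], same dim as `volume`.
#' @export
predict_volume <- function(model, volume, tile_shape = NULL, overlap = 8) {
  stopifnot(inherits(model, "unet3d_model"))
  x <- normalize_intensity(volume)
  if (is.null(tile_shape)) {
    return(unet_forward(model, x)$S)
  }
  tile_shape <- as.integer(rep(tile_shape, length.out = 3))
  check_divisible(tile_shape, model$config$levels)
  tl <- tile_volume(x, tile_shape, overlap)
  probs <- lapply(tl$tiles, function(ti) unet_forward(model, ti)$S)
  stitch_tiles(tl$grid, probs, blend = "mean")
}

#' Threshold a probability volume into a binary mask
#'
#' A voxel is foreground iff `S >= threshold` (ties count as foreground).
#'
#' @param S probability array.
#' @param threshold scalar in (0, 1).
#' @return integer 0/1 array.
#' @export
binarize <- function(S, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  array(as.integer(S >= threshold), dim = dim(S))
}
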