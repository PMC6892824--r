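#' @title Spatially constrained CycleGAN for microscopy synthesis
#' @name spcyclegan
#' @description Learns, from unpaired binary phantoms and real microscopy
#'   volumes, a generator mapping binary volumes to synthetic microscopy
#'   volumes. The objective couples least-squares (or cross-entropy)
#'   adversarial terms for both mapping directions with a cycle-consistency
#'   penalty and a spatial constraint: a third network segments the generated
#'   patch back to a mask, and its L2 distance to the input mask penalizes
#'   any displacement of generated structures away from the mask positions.
#'   All networks are 3D and run on patches.
NULL

#' GAN configuration
#'
#' @param patch_shape (z, y, x) training patch size; divisible by
#'   2^(levels-1), the generators' total downsampling factor.
#' @param levels resolution levels of the generator U-Nets.
#' @param base_channels first-level channel width of the generators.
#' @param disc_channels first-level channel width of the discriminators.
#' @param cycle_weight weight of the cycle-consistency L1 term (>= 0).
#' @param spatial_constraint_weight weight of the spatial L2 term (>= 0);
#'   defaults to `cycle_weight`.
#' @param adv_loss "least-squares" (default, stable) or "cross-entropy".
#' @param learning_rate,beta1,beta2 Adam settings for all networks.
#' @param epochs passes over the patch pools.
#' @param seed RNG seed (init, shuffling, patch crops).
#' @return a `gan_config` object.
#' @export
gan_config <- function(patch_shape = c(32, 32, 32), levels = 2,
                       base_channels = 8, disc_channels = 8,
                       cycle_weight = 10,
                       spatial_constraint_weight = cycle_weight,
                       adv_loss = c("least-squares", "cross-entropy"),
                       learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                       epochs = 20, seed = 1L) {
  adv_loss <- match.arg(adv_loss)
  patch_shape <- as.integer(rep(patch_shape, length.out = 3))
  if (cycle_weight < 0 || spatial_constraint_weight < 0)
    stop("loss weights must be >= 0")
  f <- 2^(levels - 1)
  if (any(patch_shape %% f != 0))
    stop("patch_shape must be divisible by the generator downsampling factor ", f)
  structure(list(patch_shape = patch_shape, levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 disc_channels = as.integer(disc_channels),
                 cycle_weight = cycle_weight,
                 spatial_constraint_weight = spatial_constraint_weight,
                 adv_loss = adv_loss, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "gan_config")
}

# PatchGAN-style discriminator: two stride-2 reductions, linear patch logits.
disc_ops <- function(c1) {
  list(nn_conv(1, c1), nn_lrelu(0.2), nn_pool(),
       nn_conv(c1, 2 * c1), nn_lrelu(0.2), nn_pool(),
       nn_conv(2 * c1, 1))
}

# Adversarial loss on discriminator logits d with scalar target t (0/1).
adv_value <- function(d, t, kind) {
  if (kind == "least-squares") mean((d - t)^2)
  else mean(log(1 + exp(-abs(d))) + pmax(d, 0) - t * d)  # BCE with logits
}
adv_grad <- function(d, t, kind) {
  if (kind == "least-squares") 2 * (d - t) / length(d)
  else (1 / (1 + exp(-d)) - t) / length(d)
}

extract_patch <- function(vol, shape) {
  d <- dim(vol)
  if (any(shape > d)) stop("patch larger than volume")
  o <- vapply(1:3, function(a)
    if (d[a] == shape[a]) 0L else sample.int(d[a] - shape[a] + 1, 1) - 1L,
    integer(1))
  vol[o[1] + seq_len(shape[1]), o[2] + seq_len(shape[2]),
      o[3] + seq_len(shape[3]), drop = FALSE]
}

#' Train the spatially constrained CycleGAN
#'
#' @param binary_volumes list of 0/1 phantom arrays (pool X).
#' @param real_volumes list of intensity arrays (pool Y, unpaired;
#'   min-max normalized internally).
#' @param config a [gan_config()].
#' @return an `spcyclegan_model` holding the binary-to-microscopy generator
#'   (plus the reverse generator, spatial segmenter and discriminators), the
#'   per-epoch loss-component history, and a provenance manifest.
#' @export
train_spcyclegan <- function(binary_volumes, real_volumes, config) {
  stopifnot(inherits(config, "gan_config"))
  if (!length(binary_volumes) || !length(real_volumes))
    stop("both volume pools must be non-empty")
  set.seed(config$seed)
  gcfg <- unet3d_config(levels = config$levels,
                        base_channels = config$base_channels)
  G <- list(ops = unet_ops(gcfg))            # binary -> microscopy
  Fn <- list(ops = unet_ops(gcfg))           # microscopy -> binary
  H <- list(ops = unet_ops(gcfg))            # spatial-constraint segmenter
  DX <- list(ops = disc_ops(config$disc_channels))
  DY <- list(ops = disc_ops(config$disc_channels))
  st <- list(G = nn_init_adam(G), F = nn_init_adam(Fn), H = nn_init_adam(H),
             DX = nn_init_adam(DX), DY = nn_init_adam(DY))
  reals <- lapply(real_volumes, normalize_intensity)
  ps <- config$patch_shape
  kind <- config$adv_loss
  cw <- config$cycle_weight
  sw <- config$spatial_constraint_weight
  lr <- config$learning_rate
  n_steps <- max(length(binary_volumes), length(reals))
  hist <- NULL
  t_adam <- 0
  for (ep in seq_len(config$epochs)) {
    ix <- sample(rep_len(seq_along(binary_volumes), n_steps))
    iy <- sample(rep_len(seq_along(reals), n_steps))
    comp <- c(adv_G = 0, adv_F = 0, cycle = 0, spatial = 0,
              d_x = 0, d_y = 0)
    for (s in seq_len(n_steps)) {
      x <- vol_to_feat(extract_patch(binary_volumes[[ix[s]]], ps))
      y <- vol_to_feat(extract_patch(reals[[iy[s]]], ps))
      # ---- forward ----
      fx  <- net_forward(G, x, ps)           # G(x)
      fy  <- net_forward(Fn, y, ps)          # F(y)
      cyx <- net_forward(Fn, fx$out, ps)     # F(G(x))
      cyy <- net_forward(G, fy$out, ps)      # G(F(y))
      hgx <- net_forward(H, fx$out, ps)      # H(G(x))
      dyg <- net_forward(DY, fx$out, ps)
      dxf <- net_forward(DX, fy$out, ps)
      n_el <- length(x)
      adv_G <- adv_value(dyg$out, 1, kind)
      adv_F <- adv_value(dxf$out, 1, kind)
      cyc <- cw * (mean(abs(cyx$out - x)) + mean(abs(cyy$out - y)))
      spat <- sw * mean((hgx$out - x)^2)
      # ---- generator-side gradients ----
      gG <- nn_zero_grads(G); gF <- nn_zero_grads(Fn); gH <- nn_zero_grads(H)
      d_fx <- net_backward(DY, dyg$caches, adv_grad(dyg$out, 1, kind))$dx
      if (cw > 0) {
        bF <- net_backward(Fn, cyx$caches, cw * sign(cyx$out - x) / n_el)
        gF <- nn_add_grads(gF, bF$grads)
        d_fx <- d_fx + bF$dx
      }
      if (sw > 0) {
        bH <- net_backward(H, hgx$caches, sw * 2 * (hgx$out - x) / n_el)
        gH <- nn_add_grads(gH, bH$grads)
        d_fx <- d_fx + bH$dx
      }
      gG <- nn_add_grads(gG, net_backward(G, fx$caches, d_fx)$grads)
      d_fy <- net_backward(DX, dxf$caches, adv_grad(dxf$out, 1, kind))$dx
      if (cw > 0) {
        bG <- net_backward(G, cyy$caches, cw * sign(cyy$out - y) / n_el)
        gG <- nn_add_grads(gG, bG$grads)
        d_fy <- d_fy + bG$dx
      }
      gF <- nn_add_grads(gF, net_backward(Fn, fy$caches, d_fy)$grads)
      t_adam <- t_adam + 1
      u <- nn_adam_step(G, gG, st$G, lr, config$beta1, config$beta2, t = t_adam)
      G <- u$net; st$G <- u$state
      u <- nn_adam_step(Fn, gF, st$F, lr, config$beta1, config$beta2, t = t_adam)
      Fn <- u$net; st$F <- u$state
      if (sw > 0) {
        u <- nn_adam_step(H, gH, st$H, lr, config$beta1, config$beta2, t = t_adam)
        H <- u$net; st$H <- u$state
      }
      # ---- discriminators (generated patches detached) ----
      dyr <- net_forward(DY, y, ps)
      dyf <- net_forward(DY, fx$out, ps)
      d_y <- 0.5 * (adv_value(dyr$out, 1, kind) + adv_value(dyf$out, 0, kind))
      gDY <- nn_add_grads(
        nn_zero_grads(DY),
        net_backward(DY, dyr$caches, 0.5 * adv_grad(dyr$out, 1, kind))$grads)
      gDY <- nn_add_grads(
        gDY, net_backward(DY, dyf$caches, 0.5 * adv_grad(dyf$out, 0, kind))$grads)
      u <- nn_adam_step(DY, gDY, st$DY, lr, config$beta1, config$beta2, t = t_adam)
      DY <- u$net; st$DY <- u$state
      dxr <- net_forward(DX, x, ps)
      dxg <- net_forward(DX, fy$out, ps)
      d_x <- 0.5 * (adv_value(dxr$out, 1, kind) + adv_value(dxg$out, 0, kind))
      gDX <- nn_add_grads(
        nn_zero_grads(DX),
        net_backward(DX, dxr$caches, 0.5 * adv_grad(dxr$out, 1, kind))$grads)
      gDX <- nn_add_grads(
        gDX, net_backward(DX, dxg$caches, 0.5 * adv_grad(dxg$out, 0, kind))$grads)
      u <- nn_adam_step(DX, gDX, st$DX, lr, config$beta1, config$beta2, t = t_adam)
      DX <- u$net; st$DX <- u$state
      comp <- comp + c(adv_G, adv_F, cyc, spat, d_x, d_y) / n_steps
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, adv_G = comp["adv_G"], adv_F = comp["adv_F"],
      cycle = comp["cycle"], spatial = comp["spatial"],
      gen_total = comp["adv_G"] + comp["adv_F"] + comp["cycle"] +
        comp["spatial"],
      d_x = comp["d_x"], d_y = comp["d_y"], row.names = NULL))
  }
  structure(list(G = G, F = Fn, H = H, DX = DX, DY = DY, config = config,
                 history = hist,
                 manifest = list(seed = config$seed, epochs = config$epochs,
                                 n_binary = length(binary_volumes),
                                 n_real = length(reals))),
            class = "spcyclegan_model")
}

#' Synthesize a microscopy volume from a binary phantom
#'
#' Deterministic for a fixed trained model; volumes whose dims are not
#' divisible by the generator's downsampling factor are tiled with the
#' training patch shape and stitched with mean blending.
#'
#' @param model an `spcyclegan_model`.
#' @param binary 0/1 array.
#' @return intensity array in \[0, 1\], same dim as `binary`.
#' @export
synthesize <- function(model, binary) {
  stopifnot(inherits(model, "spcyclegan_model"))
  validate_volume(binary, "binary")
  dims <- dim(binary)
  f <- 2^(model$config$levels - 1)
  if (all(dims %% f == 0)) {
    r <- net_forward(model$G, vol_to_feat(binary), as.integer(dims))
    return(feat_to_vol(r$out, dims))
  }
  ts <- pmin(model$config$patch_shape, (dims %/% f) * f)
  if (any(ts == 0))
    stop("volume too small for the generator downsampling factor ", f)
  tl <- tile_volume(binary, ts, overlap = f)
  outs <- lapply(tl$tiles, function(ti) {
    r <- net_forward(model$G, vol_to_feat(ti), as.integer(dim(ti)))
    feat_to_vol(r$out, dim(ti))
  })
  stitch_tiles(tl$grid, outs, blend = "mean")
}

#' Build spatially registered training pairs by 2x2x2 subdivision
#'
#' Each phantom is synthesized into a microscopy volume (by a trained GAN
#' generator or, with a [render_config()], by the classical renderer) and
#' both volumes are split into 8 octants, giving `n_volumes x 8` registered
#' (binary, intensity) pairs.
#'
#' @param mask_dataset a `mask_dataset`.
#' @param synthesizer an `spcyclegan_model` or a `render_config`.
#' @param subdivision per-axis split counts (default c(2, 2, 2)).
#' @return list of pairs, each `list(binary =, intensity =, volume =, octant =)`.
#' @export
build_training_pairs <- function(mask_dataset, synthesizer,
                                 subdivision = c(2, 2, 2)) {
  stopifnot(inherits(mask_dataset, "mask_dataset"))
  subdivision <- as.integer(subdivision)
  pairs <- list()
  for (v in seq_along(mask_dataset$volumes)) {
    entry <- mask_dataset$volumes[[v]]
    synth <- synthesize_any(synthesizer, entry, v)
    pieces_b <- subdivide_volume(entry$binary, subdivision)
    pieces_i <- subdivide_volume(synth, subdivision)
    for (k in seq_along(pieces_b)) {
      pairs[[length(pairs) + 1]] <-
        list(binary = pieces_b[[k]], intensity = pieces_i[[k]],
             volume = v, octant = k)
    }
  }
  pairs
}

synthesize_any <- function(synthesizer, entry, index) {
  if (inherits(synthesizer, "spcyclegan_model")) {
    synthesize(synthesizer, entry$binary)
  } else if (inherits(synthesizer, "render_config")) {
    cfg <- synthesizer
    cfg$seed <- derive_seed(synthesizer$seed, paste0("render_", index))
    render_volume(entry$labels, cfg)
  } else stop("synthesizer must be an spcyclegan_model or render_config")
}

# Split a volume into prod(subdivision) equal blocks (dims must divide).
subdivide_volume <- function(volume, subdivision = c(2, 2, 2)) {
  d <- dim(volume)
  if (any(d %% subdivision != 0))
    stop("volume dims must be divisible by the subdivision")
  bs <- d %/% subdivision
  out <- list()
  for (bx in seq_len(subdivision[3])) for (by in seq_len(subdivision[2]))
    for (bz in seq_len(subdivision[1])) {
      out[[length(out) + 1]] <- volume[
        (bz - 1) * bs[1] + seq_len(bs[1]),
        (by - 1) * bs[2] + seq_len(bs[2]),
        (bx - 1) * bs[3] + seq_len(bs[3]), drop = FALSE]
    }
  out
}
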