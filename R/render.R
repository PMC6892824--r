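#' @title Classical microscopy degradation renderer
#' @name microscopy_render
#' @description Turns a labeled phantom into a plausible fluorescence
#'   intensity volume by composing the dominant degradations of deep-tissue
#'   imaging: per-nucleus brightness jitter, anisotropic point-spread blur,
#'   radial vignetting, loss of contrast with depth, background offset and
#'   sensor noise. It both provides a CPU-scale synthesis backend for the
#'   pipeline and generates "real-like" volumes for exercising the GAN.
NULL

#' Renderer configuration
#'
#' Intensities are on a normalized \[0, 1\] scale.
#'
#' @param foreground_mean mean nucleus intensity (> background_level).
#' @param intensity_jitter fractional per-nucleus brightness jitter (uniform
#'   in +/- this fraction of foreground contrast).
#' @param background_level additive background intensity (>= 0).
#' @param psf_sigma Gaussian blur sigma (sz, sy, sx) in voxels; axial sigma
#'   is typically the largest, mirroring the microscope PSF.
#' @param vignetting_strength fractional corner darkening per slice, in
#'   \[0, 1): 0 disables vignetting.
#' @param depth_decay per-slice multiplicative contrast loss in \[0, 1):
#'   contrast at slice z is scaled by (1 - depth_decay)^z.
#' @param noise_model "gaussian" (additive, sd = `noise_sd`) or
#'   "poisson_gaussian" (shot noise with `photons_at_fullscale` photons at
#'   intensity 1, plus additive read noise sd = `noise_sd`).
#' @param noise_sd additive noise standard deviation.
#' @param photons_at_fullscale photon count mapping for shot noise.
#' @param seed integer RNG seed.
#' @return a `render_config` object.
#' @export
render_config <- function(foreground_mean = 0.75,
                          intensity_jitter = 0.15,
                          background_level = 0.08,
                          psf_sigma = c(1.6, 1.0, 1.0),
                          vignetting_strength = 0.25,
                          depth_decay = 0.005,
                          noise_model = c("gaussian", "poisson_gaussian"),
                          noise_sd = 0.067,
                          photons_at_fullscale = 400,
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (foreground_mean <= background_level)
    stop("foreground_mean must exceed background_level")
  if (background_level < 0) stop("background_level must be >= 0")
  if (any(psf_sigma < 0)) stop("psf_sigma must be >= 0")
  if (vignetting_strength < 0 || vignetting_strength >= 1)
    stop("vignetting_strength must be in [0, 1)")
  if (depth_decay < 0 || depth_decay >= 1)
    stop("depth_decay must be in [0, 1)")
  structure(list(foreground_mean = foreground_mean,
                 intensity_jitter = intensity_jitter,
                 background_level = background_level,
                 psf_sigma = as.numeric(psf_sigma),
                 vignetting_strength = vignetting_strength,
                 depth_decay = depth_decay,
                 noise_model = noise_model,
                 noise_sd = noise_sd,
                 photons_at_fullscale = photons_at_fullscale,
                 seed = as.integer(seed)),
            class = "render_config")
}

#' Render a labeled phantom into a microscopy-like intensity volume
#'
#' Pipeline: per-instance base intensity (jittered) -> anisotropic Gaussian
#' blur -> radial cosine vignetting per slice -> exponential depth decay of
#' contrast -> additive background -> noise -> clip to \[0, 1\]. Identical
#' seed gives identical output.
#'
#' @param labels integer label array (0 = background).
#' @param config a [render_config()].
#' @return numeric intensity array in \[0, 1\], same dim as `labels`.
#' @export
render_volume <- function(labels, config) {
  stopifnot(inherits(config, "render_config"))
  validate_volume(labels, "label")
  vs <- dim(labels)
  set.seed(config$seed)
  contrast <- config$foreground_mean - config$background_level
  n_inst <- max(labels)
  base <- if (n_inst > 0) {
    contrast * (1 + runif(n_inst, -config$intensity_jitter,
                          config$intensity_jitter))
  } else numeric(0)
  sig <- array(0, dim = vs)
  if (n_inst > 0) {
    fg <- labels > 0L
    sig[fg] <- base[labels[fg]]
  }
  sig <- nsg_gauss_blur3(sig, as.integer(vs), config$psf_sigma)
  # radial cosine vignetting field, identical for every slice
  if (config$vignetting_strength > 0) {
    yy <- (seq_len(vs[2]) - (vs[2] + 1) / 2) / (vs[2] / 2)
    xx <- (seq_len(vs[3]) - (vs[3] + 1) / 2) / (vs[3] / 2)
    r <- sqrt(outer(yy^2, xx^2, `+`)) / sqrt(2)   # 0 center .. 1 corner
    vign <- 1 - config$vignetting_strength * (1 - cos(pi * pmin(r, 1) / 2))
    sig <- sweep(sig, c(2, 3), vign, `*`)
  }
  if (config$depth_decay > 0) {
    decay <- (1 - config$depth_decay)^(seq_len(vs[1]) - 1)
    sig <- sweep(sig, 1, decay, `*`)
  }
  out <- sig + config$background_level
  if (config$noise_model == "gaussian") {
    if (config$noise_sd > 0)
      out <- out + rnorm(length(out), sd = config$noise_sd)
  } else {
    ph <- config$photons_at_fullscale
    out <- rpois(length(out), lambda = pmax(out, 0) * ph) / ph
    if (config$noise_sd > 0)
      out <- out + rnorm(length(out), sd = config$noise_sd)
  }
  array(pmin(pmax(out, 0), 1), dim = vs)
}

#' Render the deterministic pre-noise signal (no noise, for diagnostics)
#' @inheritParams render_volume
#' @return intensity array before the noise stage (still clipped to \[0,1\]).
#' @keywords internal
render_prenoise <- function(labels, config) {
  cfg <- config
  cfg$noise_sd <- 0
  cfg$noise_model <- "gaussian"
  render_volume(labels, cfg)
}

#' Render an unpaired pool of intensity volumes from a phantom dataset
#'
#' Used to emulate the "real microscopy" side of unpaired GAN training: the
#' volumes come from distinct phantoms and no pairing information is kept.
#'
#' @param mask_dataset a `mask_dataset` from [generate_mask_dataset()].
#' @param config a [render_config()]; per-volume seeds derive from its seed.
#' @param n number of volumes (<= dataset size).
#' @return list of intensity arrays, with per-volume seeds as an attribute.
#' @export
render_unpaired_pool <- function(mask_dataset, config, n) {
  stopifnot(inherits(mask_dataset, "mask_dataset"))
  if (n > length(mask_dataset$volumes))
    stop("n exceeds dataset size")
  seeds <- vapply(seq_len(n), function(i)
    derive_seed(config$seed, paste0("pool_", i)), integer(1))
  out <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    render_volume(mask_dataset$volumes[[i]]$labels, cfg)
  })
  attr(out, "seeds") <- seeds
  out
}
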