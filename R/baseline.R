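#' @title Otsu + 3D watershed classical baseline
#' @name baseline_classical
#' @description The reference segmentation the learned pipeline is compared
#'   against: a global Otsu threshold over the full-volume histogram followed
#'   by a 3D distance-transform watershed with h-maxima markers. Fully
#'   deterministic.
NULL

#' Otsu threshold of an intensity volume
#'
#' The volume's full histogram (over `n_bins` equal-width bins spanning its
#' min-max range) is scanned for the inter-bin split maximizing the
#' between-class variance `w0*w1*(mu0-mu1)^2`; ties resolve to the lower bin.
#'
#' @param volume intensity array; must not be constant.
#' @param n_bins histogram bins (default 256).
#' @return a list of class `otsu_result` with `threshold` (intensity value:
#'   the bin edge of the chosen split), `histogram` (bin counts), `edges`,
#'   `variance_curve` (between-class variance per candidate split) and
#'   `mask` (integer 0/1 array, `volume >= threshold`).
#' @export
otsu_threshold <- function(volume, n_bins = 256) {
  v <- as.vector(volume)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("degenerate input: volume is constant")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / length(v)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)[-n_bins]                   # split after bin t, t = 1..n-1
  mu_cum <- cumsum(p * mids)[-n_bins]
  mu_tot <- sum(p * mids)
  w1 <- 1 - w0
  sb2 <- ifelse(w0 > 0 & w1 > 0,
                (mu_tot * w0 - mu_cum)^2 / (w0 * w1), 0)
  t_star <- which.max(sb2)                   # which.max takes the lowest tie
  thr <- edges[t_star + 1]
  res <- structure(list(threshold = thr, histogram = counts, edges = edges,
                        variance_curve = sb2,
                        mask = array(as.integer(volume >= thr), dim(volume))),
                   class = "otsu_result")
  res
}

#' 3D distance-transform watershed of a binary mask
#'
#' The exact 3D Euclidean distance transform of the (hole-filled) mask is
#' flooded with merge tolerance `marker_h` (the h-maxima marker depth);
#' voxels where surviving basins meet are removed from the original mask and
#' the remainder relabeled by face-connected components, giving deterministic
#' raster-order label ids.
#'
#' @param mask 0/1 array.
#' @param marker_h h-maxima depth in voxels.
#' @param min_size minimum object size in voxels (0 keeps everything).
#' @return integer label array; foreground is a subset of the input mask.
#' @export
watershed3d <- function(mask, marker_h = 2, min_size = 0) {
  validate_volume(mask, "binary")
  if (!any(mask > 0)) return(array(0L, dim(mask)))
  dm <- as.integer(dim(mask))
  # interior noise holes crater the distance transform and spawn spurious
  # maxima; fill them for marker detection only (output stays within `mask`)
  filled <- round(EBImage::fillHull(array(as.numeric(mask > 0), dim(mask))))
  d <- mask_edt3(filled)
  ws <- nsg_tol_watershed(as.numeric(d), array(as.integer(filled), dim(mask)),
                          dm, marker_h)
  keep <- array(as.integer(mask > 0 & !ws$boundary), dim(mask))
  # face connectivity so removed basin interfaces cannot reconnect diagonally
  labs <- nsg_cc_label3(keep, dm, 6L)
  filter_small_labels(labs, min_size)
}

# Exact 3D Euclidean distance of each foreground voxel to the nearest
# background voxel (the height map the 3D watershed floods).
mask_edt3 <- function(mask) {
  d <- dim(mask)
  bg <- array(as.integer(mask == 0), d)
  if (!any(bg == 1)) return(array(sqrt(sum(d^2)), d))
  r <- nsg_nearest_label_edt(bg, as.integer(d))
  array(sqrt(r$dist2), d)
}

#' Run the Otsu + 3D watershed baseline on an intensity volume
#'
#' @param volume intensity array.
#' @param n_bins Otsu histogram bins.
#' @param marker_h watershed h-maxima depth.
#' @param min_size minimum object size (kept equal to the learned pipeline's
#'   default for comparability).
#' @return integer label array with an attribute `params` logging all
#'   parameters and the chosen threshold.
#' @export
run_baseline <- function(volume, n_bins = 256, marker_h = 2, min_size = 27) {
  ot <- otsu_threshold(volume, n_bins)
  labs <- watershed3d(ot$mask, marker_h, min_size)
  attr(labs, "params") <- list(n_bins = n_bins, threshold = ot$threshold,
                               marker_h = marker_h, min_size = min_size)
  labs
}
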