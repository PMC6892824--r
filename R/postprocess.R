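#' @title Quasi-3D watershed instance separation
#' @name postprocess
#' @description Converts the binary CNN output into instance labels: a 2D
#'   distance-transform watershed runs per slice, sequentially in each of the
#'   three orthogonal plane orientations; the split lines from all passes are
#'   accumulated, removed from the mask, and the remainder is 3D
#'   26-connected-component labeled. Optional competitive label dilation
#'   grows instances outward for cytometry sampling without ever merging them.
NULL

#' Watershed configuration
#'
#' @param plane_order orientations to process, a permutation of
#'   c("xy", "xz", "yz").
#' @param h h-maxima depth (the watershed merge tolerance) on the 2D distance
#'   transform, in voxels (> 0).
#' @param min_size minimum surviving object size in voxels.
#' @return a `watershed_config` object.
#' @export
watershed_config <- function(plane_order = c("xy", "xz", "yz"), h = 2,
                             min_size = 27) {
  if (!setequal(plane_order, c("xy", "xz", "yz")))
    stop("plane_order must be a permutation of xy, xz, yz")
  if (h <= 0) stop("h must be > 0")
  structure(list(plane_order = plane_order, h = h,
                 min_size = as.integer(min_size)),
            class = "watershed_config")
}

# Split-line pixels of one slice: the slice's in-plane holes are filled (so
# interior noise does not crater the distance transform), the 2D Euclidean
# distance transform is flooded with tolerance h, and pixels where surviving
# basins meet are returned. Lines are later applied to the original mask, so
# no foreground is ever created.
slice_split_lines <- function(m, h) {
  if (!any(m > 0)) return(matrix(FALSE, nrow(m), ncol(m)))
  filled <- round(EBImage::fillHull(matrix(as.numeric(m > 0), nrow(m))))
  dims <- c(1L, nrow(m), ncol(m))
  d <- mask_edt3(array(filled, dims))
  ws <- nsg_tol_watershed(as.numeric(d), array(as.integer(filled), dims),
                          dims, h)
  matrix(as.vector(ws$boundary), nrow(m), ncol(m))
}

#' Quasi-3D watershed: split touching nuclei into instances
#'
#' @param mask 0/1 array (z, y, x), typically the thresholded CNN output.
#' @param cfg a [watershed_config()].
#' @return integer label array; label ids are assigned in raster-scan order
#'   of each object's first voxel, so output is bit-reproducible. Foreground
#'   of the output is a subset of the input foreground.
#' @export
quasi3d_watershed <- function(mask, cfg = watershed_config()) {
  validate_volume(mask, "binary")
  stopifnot(inherits(cfg, "watershed_config"))
  d <- dim(mask)
  split <- array(FALSE, d)
  for (orient in cfg$plane_order) {
    if (orient == "xy") {
      for (z in seq_len(d[1]))
        split[z, , ] <- split[z, , ] | slice_split_lines(mask[z, , ], cfg$h)
    } else if (orient == "xz") {
      for (y in seq_len(d[2]))
        split[, y, ] <- split[, y, ] | slice_split_lines(mask[, y, ], cfg$h)
    } else {
      for (x in seq_len(d[3]))
        split[, , x] <- split[, , x] | slice_split_lines(mask[, , x], cfg$h)
    }
  }
  keep <- array(as.integer(mask > 0 & !split), d)
  # Face connectivity for the relabeling: the accumulated split lines are
  # one-voxel-thick surfaces, and diagonal (26-neighbor) adjacency would
  # reconnect the very basins they separate. Face-connected components are
  # of course still 26-connected label sets.
  labs <- nsg_cc_label3(keep, as.integer(d), 6L)
  filter_small_labels(labs, cfg$min_size)
}

# Drop labels below min_size voxels and compress ids (ascending id order is
# raster order already, which nsg_cc_label3 guarantees).
filter_small_labels <- function(labs, min_size) {
  n <- max(labs)
  if (n == 0 || min_size <= 1) return(labs)
  sizes <- tabulate(labs[labs > 0], nbins = n)
  keep <- sizes >= min_size
  map <- integer(n)
  map[keep] <- seq_len(sum(keep))
  out <- labs
  fg <- labs > 0
  out[fg] <- map[labs[fg]]
  out
}

#' Competitively dilate instance labels
#'
#' Each label grows outward by at most `radius` voxels (Euclidean); contested
#' voxels go to the nearest label, so distinct instances never merge.
#' Radius 0 is the identity.
#'
#' @param labels integer label array.
#' @param radius dilation radius in voxels (>= 0).
#' @return integer label array containing the original labels plus their
#'   dilated shells.
#' @export
dilate_labels <- function(labels, radius) {
  validate_volume(labels, "label")
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0 || max(labels) == 0) return(labels)
  r <- nsg_nearest_label_edt(array(as.integer(labels), dim(labels)),
                             as.integer(dim(labels)))
  out <- r$label
  out[r$dist2 > radius^2] <- 0L
  array(out, dim(labels))
}
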