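#' @title Volume I/O and tiling
#' @name volumes_io
#' @description Read/write 3D volumes as multi-page grayscale TIFF and tile /
#'   stitch them for processing volumes larger than one network input.
#'   Axis order is fixed as (z, y, x); TIFF page index is z. Tile offsets are
#'   0-based and ranges half-open.
NULL

#' Validate a 3D volume array for a given role
#'
#' @param volume numeric/integer 3D array, dim = c(z, y, x).
#' @param role one of "intensity", "binary", "label".
#' @return the volume, invisibly, after validation.
#' @export
validate_volume <- function(volume, role = c("intensity", "binary", "label")) {
  role <- match.arg(role)
  if (length(dim(volume)) != 3L)
    stop("volume must be a 3D array (z, y, x)")
  if (role == "binary") {
    u <- unique(as.vector(volume))
    bad <- setdiff(u, c(0, 1))
    if (length(bad))
      stop("binary volume contains value(s) outside {0,1}: ", bad[1])
  }
  if (role == "label") {
    v <- as.vector(volume)
    if (any(v < 0))
      stop("label volume contains negative value: ", min(v))
    if (any(v != round(v)))
      stop("label volume contains non-integer value")
  }
  invisible(volume)
}

#' Read a 3D volume from a multi-page TIFF stack
#'
#' Pages map to z-slices; the returned array has dim = c(pages, height, width).
#' Integer-typed files are read bit-exactly (`as.is`), float files as stored.
#'
#' @param path file path to a multi-page TIFF.
#' @param role volume role used for validation: "intensity" (default),
#'   "binary" (values must be 0/1) or "label" (non-negative integers).
#' @return a 3D array with dim = c(z, y, x).
#' @export
read_volume <- function(path, role = c("intensity", "binary", "label")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("cannot read volume, no such file: ", path)
  # integer samples are read unscaled (bit-exact); float samples as stored
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) stop("unreadable TIFF '", path, "': ",
                                            conditionMessage(e)))
  # 8/16-bit samples are integer grayscale; 32-bit samples are float pages
  is_float <- isTRUE(info$bits.per.sample[1] >= 32)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = !is_float),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  z <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  vol <- array(0, dim = c(z, h, w))
  for (i in seq_len(z)) vol[i, , ] <- pages[[i]]
  if (role == "label") vol <- array(round(vol), dim = dim(vol))
  validate_volume(vol, role)
  vol
}

#' Write a 3D volume as a multi-page TIFF stack
#'
#' Integer classes round-trip bit-exactly; float32 volumes round-trip to
#' within single precision.
#'
#' @param volume 3D array, dim = c(z, y, x).
#' @param path output file path.
#' @param dtype_class "uint8", "uint16" or "float".
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dtype_class = c("uint16", "uint8", "float")) {
  dtype_class <- match.arg(dtype_class)
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  v <- as.vector(volume)
  if (dtype_class != "float") {
    cap <- if (dtype_class == "uint8") 255 else 65535
    if (any(v < 0) || any(v > cap))
      stop("value range [", min(v), ", ", max(v), "] exceeds ", dtype_class,
           " range [0, ", cap, "]")
    if (any(v != round(v)))
      stop("non-integer values cannot be written as ", dtype_class)
    pages <- lapply(seq_len(dim(volume)[1]),
                    function(z) volume[z, , ] / cap)
    tiff::writeTIFF(pages, path,
                    bits.per.sample = if (dtype_class == "uint8") 8L else 16L,
                    compression = "none")
  } else {
    pages <- lapply(seq_len(dim(volume)[1]), function(z) {
      m <- volume[z, , ]
      storage.mode(m) <- "double"
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  invisible(path)
}

#' Write a label volume as uint16 TIFF
#'
#' Grayscale TIFF caps instance ids at 65535 per volume; larger label ranges
#' are rejected rather than stored lossily (process such volumes in tiles).
#'
#' @inheritParams write_volume
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  validate_volume(volume, "label")
  if (max(volume) > 65535)
    stop("more than 65535 labels cannot be stored in a uint16 TIFF; ",
         "relabel or process the volume in tiles")
  write_volume(volume, path, "uint16")
  invisible(path)
}

# 1D covering offsets: start positions of windows of length `tile` with at
# least `overlap` shared voxels between consecutive windows, covering [0, n).
covering_offsets_1d <- function(n, tile, overlap) {
  if (tile > n) stop("tile size ", tile, " exceeds volume extent ", n)
  if (overlap >= tile) stop("overlap must be smaller than tile size")
  step <- tile - overlap
  starts <- seq(0L, max(0L, n - tile), by = step)
  if (tail(starts, 1) + tile < n) starts <- c(starts, n - tile)
  as.integer(starts)
}

#' Tile a volume into overlapping sub-volumes
#'
#' @param volume 3D array.
#' @param tile_shape integer (z, y, x) tile size; each entry must not exceed
#'   the corresponding volume extent.
#' @param overlap integer voxels of overlap per axis (scalar or length 3).
#' @return a list with `grid` (a `tile_grid` with `tile_shape`, `overlap`,
#'   `offsets` matrix of 0-based tile origins, `volume_shape`) and `tiles`
#'   (list of sub-volume arrays, in the grid's row order).
#' @export
tile_volume <- function(volume, tile_shape, overlap = 0L) {
  vs <- dim(volume)
  tile_shape <- as.integer(rep(tile_shape, length.out = 3))
  overlap <- as.integer(rep(overlap, length.out = 3))
  if (any(overlap < 0)) stop("overlap must be >= 0")
  offs <- lapply(1:3, function(a) covering_offsets_1d(vs[a], tile_shape[a], overlap[a]))
  grid_off <- as.matrix(expand.grid(z = offs[[1]], y = offs[[2]], x = offs[[3]],
                                    KEEP.OUT.ATTRS = FALSE))
  tiles <- lapply(seq_len(nrow(grid_off)), function(i) {
    o <- grid_off[i, ]
    volume[o[1] + seq_len(tile_shape[1]),
           o[2] + seq_len(tile_shape[2]),
           o[3] + seq_len(tile_shape[3]), drop = FALSE]
  })
  grid <- structure(list(tile_shape = tile_shape, overlap = overlap,
                         offsets = grid_off, volume_shape = vs),
                    class = "tile_grid")
  list(grid = grid, tiles = tiles)
}

#' Stitch tiles back into a full volume
#'
#' Overlapping voxels are combined with the chosen blend: "mean" (default for
#' probability maps; averages all covering tiles) or "max".
#'
#' @param tile_grid a `tile_grid` from [tile_volume()].
#' @param tiles list of tile arrays conforming to the grid.
#' @param blend "mean" or "max".
#' @return the stitched 3D array with the grid's original volume shape.
#' @export
stitch_tiles <- function(tile_grid, tiles, blend = c("mean", "max")) {
  blend <- match.arg(blend)
  if (!inherits(tile_grid, "tile_grid")) stop("tile_grid must come from tile_volume()")
  n <- nrow(tile_grid$offsets)
  if (length(tiles) != n)
    stop("tile count mismatch: grid has ", n, " tiles, got ", length(tiles))
  vs <- tile_grid$volume_shape
  ts <- tile_grid$tile_shape
  acc <- array(if (blend == "max") -Inf else 0, dim = vs)
  cnt <- array(0L, dim = vs)
  for (i in seq_len(n)) {
    ti <- tiles[[i]]
    if (!all(dim(ti) == ts)) stop("tile ", i, " does not conform to the grid")
    o <- tile_grid$offsets[i, ]
    iz <- o[1] + seq_len(ts[1]); iy <- o[2] + seq_len(ts[2]); ix <- o[3] + seq_len(ts[3])
    if (blend == "mean") {
      acc[iz, iy, ix] <- acc[iz, iy, ix] + ti
      cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1L
    } else {
      acc[iz, iy, ix] <- pmax(acc[iz, iy, ix], ti)
      cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1L
    }
  }
  if (any(cnt == 0L)) stop("tile grid does not cover the volume")
  if (blend == "mean") acc / cnt else acc
}
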