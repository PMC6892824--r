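test_that("integer volumes round-trip bit-exactly through TIFF", {
  set.seed(5)
  v16 <- array(sample(0:65535, 4 * 5 * 6, TRUE), c(4, 5, 6))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v16, f, "uint16")
  expect_identical(read_volume(f, "intensity"), array(as.numeric(v16), dim(v16)))

  vb <- array(sample(0:1, 3 * 4 * 4, TRUE), c(3, 4, 4))
  fb <- withr::local_tempfile(fileext = ".tif")
  write_volume(vb, fb, "uint8")
  r <- read_volume(fb, "binary")
  expect_true(all(r %in% c(0, 1)))
  expect_equal(r, array(as.numeric(vb), dim(vb)))
})

test_that("a 10-page stack reads with shape (10, 32, 32)", {
  v <- array(runif(10 * 32 * 32), c(10, 32, 32))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f, "float")
  r <- read_volume(f, "intensity")
  expect_equal(dim(r), c(10, 32, 32))
  expect_lt(max(abs(r - v)), 1e-6)
})

test_that("role validation rejects malformed volumes", {
  v <- array(0L, c(2, 2, 2)); v[1] <- -1L
  expect_error(validate_volume(v, "label"), "negative")
  v2 <- array(0, c(2, 2, 2)); v2[1] <- 0.5
  expect_error(validate_volume(v2, "binary"), "outside")
  expect_error(read_volume(file.path(tempdir(), "missing.tif")), "no such file")
})

test_that("write_volume range checks reject overflow", {
  big <- array(70000L, c(2, 2, 2))
  expect_error(write_volume(big, tempfile(), "uint16"), "exceeds")
  expect_error(write_label_volume(big, tempfile()), "65535")
  f <- withr::local_tempfile(fileext = ".tif")
  write_label_volume(array(65535L, c(2, 2, 2)), f)
  expect_equal(read_volume(f, "label")[1], 65535)
})

test_that("a 128^3 volume tiles into exactly 8 subvolumes at half size", {
  v <- array(0, c(128, 128, 128))
  tl <- tile_volume(v, c(64, 64, 64), overlap = 0)
  expect_equal(length(tl$tiles), 8L)
  expect_equal(nrow(tl$grid$offsets), 8L)
})

test_that("tiling a volume by itself yields one identical tile", {
  v <- array(runif(4^3), c(4, 4, 4))
  tl <- tile_volume(v, c(4, 4, 4))
  expect_equal(length(tl$tiles), 1L)
  expect_equal(tl$tiles[[1]], v)
  expect_error(tile_volume(v, c(8, 4, 4)), "exceeds")
})

test_that("tile counts match the 1D covering oracle across settings", {
  cases <- list(c(100, 64, 16), c(100, 64, 0), c(65, 64, 8), c(48, 16, 4),
                c(37, 16, 3))
  for (cs in cases) {
    v <- array(0, rep(cs[1], 3))
    tl <- tile_volume(v, rep(cs[2], 3), cs[3])
    expect_equal(length(tl$tiles),
                 oracle_cover_count_1d(cs[1], cs[2], cs[3])^3,
                 info = paste(cs, collapse = "/"))
  }
})

test_that("tile -> stitch is the identity and blends combine overlaps", {
  set.seed(11)
  v <- array(runif(40^3), c(40, 40, 40))
  for (ov in c(0, 7, 16)) {
    tl <- tile_volume(v, c(24, 24, 24), ov)
    expect_equal(stitch_tiles(tl$grid, tl$tiles, "mean"), v, info = ov)
    expect_equal(stitch_tiles(tl$grid, tl$tiles, "max"), v, info = ov)
  }
  # explicit blend semantics on two overlapping tiles
  v2 <- array(0, c(2, 2, 3))
  tl2 <- tile_volume(v2, c(2, 2, 2), 1)
  t1 <- array(0.2, c(2, 2, 2)); t2 <- array(0.6, c(2, 2, 2))
  mx <- stitch_tiles(tl2$grid, list(t1, t2), "max")
  mn <- stitch_tiles(tl2$grid, list(t1, t2), "mean")
  expect_equal(mx[1, 1, 2], 0.6)
  expect_equal(mn[1, 1, 2], 0.4)
  expect_error(stitch_tiles(tl2$grid, list(t1), "mean"), "mismatch")
})
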