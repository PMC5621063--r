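test_that("raster_band validates inputs and normalizes masked cells", {
  b <- raster_band(matrix(c(1, NA, 3, 4), 2, 2), pixel_size = 30)
  expect_true(b$mask[2, 1])
  expect_identical(b$values[2, 1], NA_real_)
  expect_error(raster_band(1:4), "matrix")
  expect_error(raster_band(matrix(1, 2, 2), pixel_size = -1), "positive")
  expect_error(raster_band(matrix(1, 2, 2), mask = matrix(TRUE, 1, 2)),
               "same shape")
  expect_error(validate_reflectance(raster_band(matrix(1.5, 2, 2),
                                                band = "red")),
               "outside")
  expect_true(validate_reflectance(raster_band(matrix(350, 2, 2),
                                               band = "thermal")))
})

test_that("block_aggregate averages valid cells and respects the valid-fraction rule", {
  b <- raster_band(matrix(c(1, 5, 3, 7), 2, 2))
  expect_equal(block_aggregate(b, 2)$values, matrix(4, 1, 1))
  expect_equal(block_aggregate(b, 2)$pixel_size, 2)

  const <- raster_band(matrix(0.25, 6, 6), pixel_size = 15)
  expect_equal(block_aggregate(const, 3)$values, matrix(0.25, 2, 2))

  # 3 of 4 cells masked: kept at min_valid_fraction 0.25, masked at 0.5
  m <- matrix(c(1, NA, NA, NA), 2, 2)
  expect_true(block_aggregate(raster_band(m), 2, 0.5)$mask[1, 1])
  low <- block_aggregate(raster_band(m), 2, 0.25)
  expect_false(low$mask[1, 1])
  expect_equal(low$values[1, 1], 1)

  expect_error(block_aggregate(b, 1), ">= 2")
  expect_error(block_aggregate(b, 2.5), ">= 2")
  expect_warning(block_aggregate(make_band(5, 5), 2), "cropping")
})

test_that("block_aggregate preserves the global mean of fully valid inputs", {
  b <- make_band(12, 8)
  expect_equal(mean(block_aggregate(b, 2)$values), mean(b$values),
               tolerance = 1e-14)
  expect_equal(mean(block_aggregate(b, 4)$values), mean(b$values),
               tolerance = 1e-14)
})

test_that("interpolate_upscale reproduces constants and nearest replication", {
  const <- raster_band(matrix(0.4, 3, 5))
  for (kern in c("nearest", "bilinear", "bicubic")) {
    for (s in c(2L, 3L)) {
      up <- interpolate_upscale(const, s, kern)
      expect_equal(dim(up$values), s * c(3L, 5L))
      expect_equal(up$values, matrix(0.4, 3 * s, 5 * s), tolerance = 1e-12)
      expect_equal(up$pixel_size, const$pixel_size / s)
    }
  }
  b <- raster_band(matrix(c(1, 3, 2, 4), 2, 2))
  up <- interpolate_upscale(b, 2, "nearest")
  expect_equal(up$values,
               matrix(c(1, 1, 3, 3, 1, 1, 3, 3,
                        2, 2, 4, 4, 2, 2, 4, 4), 4, 4))
  expect_error(interpolate_upscale(b, 2, "lanczos"), "nearest")
})

test_that("nearest upscaling then block aggregation is the identity", {
  b <- make_band(6, 9, seed = 3)
  for (s in c(2L, 4L)) {
    back <- block_aggregate(interpolate_upscale(b, s, "nearest"), s)
    expect_identical(back$values, b$values)
  }
})

test_that("upscaling propagates nodata pessimistically", {
  v <- matrix(0.5, 4, 4); v[2, 2] <- NA
  up <- interpolate_upscale(raster_band(v), 2, "bilinear")
  # every output cell whose bilinear footprint touches input (2,2) is masked
  expect_true(up$mask[3, 3])
  expect_true(up$mask[4, 4])
  expect_false(up$mask[1, 1])
  expect_false(any(is.na(up$values[!up$mask])))
})

test_that("residual_field is the exact complement of interpolation", {
  lr <- make_band(6, 6, seed = 5)
  up <- interpolate_upscale(lr, 2, "bicubic")
  expect_equal(residual_field(up, lr, 2, "bicubic")$values,
               matrix(0, 12, 12), tolerance = 1e-15)

  delta <- up$values; delta[5, 7] <- delta[5, 7] + 0.1
  hr <- raster_band(delta, pixel_size = up$pixel_size, band = "nir")
  r <- residual_field(hr, lr, 2, "bicubic")
  expect_equal(r$values[5, 7], 0.1)
  expect_equal(max(abs(r$values[-(5 + 6 * 12)])), 0)

  # reconstruction identity on valid cells (machine precision)
  hr2 <- make_band(12, 12, seed = 6)
  r2 <- residual_field(hr2, lr, 2, "bicubic")
  expect_equal(r2$values + up$values, hr2$values, tolerance = 1e-15)

  bad <- make_band(6, 6)
  expect_error(residual_field(make_band(6, 6), bad, 2), "shape mismatch")
  expect_error(
    residual_field(make_band(12, 12, band = "red"), make_band(6, 6), 2),
    "labels differ")
})

test_that("band I/O round-trips values, mask, and pixel size", {
  v <- matrix(runif(48, 0.1, 0.9), 6, 8)
  v[2, 3] <- NA
  b <- raster_band(v, pixel_size = 30, band = "green")
  f <- withr::local_tempfile(fileext = ".tif")
  write_band(b, f)
  b2 <- read_band(f)
  expect_equal(b2$values, b$values, tolerance = 1e-8)
  expect_identical(b2$mask, b$mask)
  expect_equal(b2$pixel_size, 30)
  expect_identical(b2$band, "green")

  # all-masked band survives the round trip
  allm <- raster_band(matrix(NA_real_, 2, 2), band = "red")
  write_band(allm, f)
  expect_true(all(read_band(f)$mask))
})

test_that("read_band honors the nodata tag from the sidecar", {
  # file holding a -9999 cell with the sidecar declaring nodata -9999
  v <- matrix(c(0.2, 0.4, -9999, 0.8), 2, 2)
  b <- raster_band(v, mask = v == -9999, pixel_size = 10, band = "red")
  f <- withr::local_tempfile(fileext = ".tif")
  write_band(b, f, nodata = -9999)
  got <- read_band(f)
  expect_identical(got$mask, matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))
  expect_equal(got$values[!got$mask], v[v != -9999], tolerance = 1e-5)
})

test_that("band I/O guards missing files, sidecars, directories, and band indices", {
  expect_error(read_band("/nonexistent/x.tif"), "no such file")
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 2, 2), f)
  expect_error(read_band(f), "sidecar")
  expect_error(write_band(make_band(2), file.path(tempdir(), "nope", "x.tif")),
               "does not exist")
  # multi-sample file: index beyond the sample count errors
  b <- make_band(4, 4)
  write_band(b, f)  # creates a valid sidecar
  suppressWarnings(tiff::writeTIFF(array(0.5, c(4, 4, 2)), f))
  expect_silent(read_band(f, index = 2))
  expect_error(read_band(f, index = 3), "out of range")
})

test_that("scene construction and I/O keep bands aligned", {
  sc <- generate_scene_pair(scene_spec(hr_shape = c(16L, 16L), seed = 2))
  expect_error(scene(list(red = make_band(4, band = "red"),
                          nir = make_band(6, band = "nir"))),
               "share shape")
  expect_error(scene(list(red = make_band(4, band = "nir"))), "label")
  d <- withr::local_tempdir()
  write_scene(sc$lr_sensor, d)
  back <- read_scene(d)
  expect_setequal(names(back$bands), BAND_LABELS)
  expect_equal(back$bands$nir$values, sc$lr_sensor$bands$nir$values,
               tolerance = 1e-7)
  expect_identical(back$platform, "coarse-sensor")
  expect_error(read_scene(d, bands = "ndvi"), "lacks band")
})
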