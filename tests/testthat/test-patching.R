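test_that("patch extraction tiles with coverage-completing origins", {
  v <- matrix(as.numeric(1:16), 4, 4, byrow = TRUE)  # v[r,c] = 4(r-1)+c
  ps <- extract_patches(raster_band(v), 2, 2)
  expect_equal(ncol(ps$vectors), 4L)
  # row-major vectorization: cells (0,0),(0,1),(1,0),(1,1)
  expect_equal(ps$vectors[, 1], c(1, 2, 5, 6))
  expect_equal(ps$origins[1, ], c(0L, 0L))

  # 5x5, p = 2, stride 2: origins {0, 2, 3} per axis -> 9 patches
  ps5 <- extract_patches(make_band(5, 5), 2, 2)
  expect_equal(ncol(ps5$vectors), 9L)
  expect_equal(unique(ps5$origins[, 1]), c(0L, 2L, 3L))

  expect_error(extract_patches(make_band(3, 3), 5), "exceeds")
})

test_that("drop_masked omits exactly the patches touching a masked cell", {
  v <- matrix(0.5, 4, 4); v[2, 2] <- NA   # 0-based cell (1,1)
  ps <- extract_patches(raster_band(v), 2, 2, drop_masked = TRUE)
  # of the 4 non-overlapping patches only the top-left contains (1,1)
  expect_equal(ncol(ps$vectors), 3L)
  expect_false(any(ps$origins[, 1] == 0 & ps$origins[, 2] == 0))
  expect_false(anyNA(ps$vectors))
})

test_that("assembly inverts extraction for partitions and overlaps", {
  b <- make_band(8, 8, seed = 21)
  for (stride in c(4L, 1L)) {   # non-overlapping partition, then maximal overlap
    back <- assemble_patches(extract_patches(b, 4, stride),
                             pixel_size = b$pixel_size, band = b$band)
    expect_equal(back$values, b$values, tolerance = 1e-15)
    expect_false(any(back$mask))
  }
})

test_that("overlap averaging takes the mean of disagreeing patches", {
  ps <- structure(list(
    vectors = cbind(rep(0.4, 4), rep(0.6, 4)),
    patch_edge = 2L, stride = 1L,
    origins = rbind(c(0L, 0L), c(0L, 1L)),
    source_shape = c(2L, 3L)), class = "patch_set")
  out <- assemble_patches(ps)
  expect_equal(out$values[1, 2], 0.5)   # shared column: midpoint
  expect_equal(out$values[1, 1], 0.4)
  expect_equal(out$values[1, 3], 0.6)
  bad <- ps; bad$source_shape <- c(2L, 2L)
  expect_error(assemble_patches(bad), "do not fit")
})

test_that("coupled dictionaries have the documented shapes and unit-norm atoms", {
  lr <- make_band(8, 8, seed = 22)
  hr <- make_band(16, 16, seed = 23)
  d <- build_coupled_dictionary(list(list(lr = lr, hr = hr)),
                                s = 2, patch_edge = 2, stride = 2)
  expect_equal(dim(d$D_l), c(4L, 16L))
  expect_equal(dim(d$D_h), c(16L, 16L))
  expect_equal(sqrt(colSums(d$D_l^2)), rep(1, 16), tolerance = 1e-12)
  expect_equal(sweep(d$D_l, 2, d$atom_norms, "*"),
               extract_patches(lr, 2, 2)$vectors)

  # exact interpolation leaves a zero residual dictionary
  up <- interpolate_upscale(lr, 2, "bicubic")
  d0 <- build_coupled_dictionary(list(list(lr = lr, hr = up)),
                                 s = 2, patch_edge = 2, stride = 2)
  expect_equal(max(abs(d0$D_h)), 0, tolerance = 1e-14)
})

test_that("three pairs at the right tiling yield 8766 training patches", {
  # 8 x 489 coarse grids, p = 3, stride 1: (8-2) * (489-2) = 2922 patch
  # pairs per date; three dates pool to 8766 columns
  prs <- lapply(1:3, function(i) {
    lr <- make_band(8, 489, seed = 30 + i)
    hr <- make_band(16, 978, seed = 40 + i)
    list(lr = lr, hr = hr)
  })
  d <- build_coupled_dictionary(prs, s = 2, patch_edge = 3, stride = 1)
  expect_equal(ncol(d$D_l), 8766L)
  expect_equal(ncol(d$D_h), 8766L)
})

test_that("training-pair permutation permutes atom columns identically", {
  prs <- synthetic_pairs("red", n = 2, hr = 16L, seed = 5)
  d12 <- build_coupled_dictionary(prs, s = 2, patch_edge = 2, stride = 2)
  d21 <- build_coupled_dictionary(rev(prs), s = 2, patch_edge = 2, stride = 2)
  m <- ncol(d12$D_l) / 2
  perm <- c((m + 1):(2 * m), 1:m)
  expect_equal(d21$D_l, d12$D_l[, perm])
  expect_equal(d21$D_h, d12$D_h[, perm])
})

test_that("coarse and fine patches cover the same ground footprint", {
  # painted-coordinate image: lr cell value encodes its 0-based origin;
  # hr is its nearest-neighbor upscale, so every hr patch must contain
  # exactly the s^2-replicated values of its lr patch
  nr <- 6L; s <- 2L; p <- 2L
  coord <- matrix(seq_len(nr * nr), nr, nr)
  lr <- raster_band(coord / (nr * nr), band = "red")
  hr <- interpolate_upscale(lr, s, "nearest")
  d <- build_coupled_dictionary(list(list(lr = lr, hr = hr)),
                                s = s, patch_edge = p, stride = 1,
                                residual = FALSE)
  for (j in seq_len(ncol(d$D_l))) {
    lr_vals <- sort(unique(d$D_l[, j] * d$atom_norms[j]))
    hr_vals <- sort(unique(d$D_h[, j]))
    expect_equal(hr_vals, lr_vals)
  }
})

test_that("dictionary construction guards degenerate inputs", {
  lr <- make_band(4, 4); hr <- make_band(8, 8)
  expect_error(build_coupled_dictionary(
    list(list(lr = lr, hr = make_band(8, 8, band = "red"))), 2, 2, 2),
    "mixed bands|labels differ")
  allm <- raster_band(matrix(NA_real_, 4, 4), band = "nir")
  expect_error(build_coupled_dictionary(
    list(list(lr = allm, hr = hr)), 2, 2, 2), "stride")
})

test_that("dictionaries round-trip through their archive format", {
  d <- build_coupled_dictionary(synthetic_pairs("nir", n = 1, hr = 16L),
                                s = 2, patch_edge = 2, stride = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  write_dictionary(d, f)
  d2 <- read_dictionary(f)
  expect_equal(d2, d)
  saveRDS(1:3, f)
  expect_error(read_dictionary(f), "coupled_dictionary")
})
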