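# Independent reference implementations used as oracles, plus small fixture
# builders. These deliberately avoid the package's own code paths.

# Naive orthogonal matching pursuit: explicit argmax loop and a
# pseudoinverse solve at every step.
naive_omp <- function(y, D, k_max, tol = 0) {
  support <- integer(0)
  r <- y
  ny <- sqrt(sum(y^2))
  coef <- numeric(0)
  while (length(support) < k_max && sqrt(sum(r^2)) > tol * ny) {
    best <- -1; best_v <- -Inf
    for (j in seq_len(ncol(D))) {
      if (j %in% support) next
      v <- abs(sum(D[, j] * r))
      if (v > best_v) { best_v <- v; best <- j }
    }
    if (best_v <= 1e-14) break
    support <- c(support, best)
    G <- D[, support, drop = FALSE]
    coef <- as.numeric(MASS::ginv(G) %*% y)
    r <- y - as.numeric(G %*% coef)
  }
  list(support = support, coefficients = coef,
       residual_norm = sqrt(sum(r^2)))
}

# Direct-summation Gaussian-PSF degradation: for every coarse cell, sum the
# fine cells under a boundary-renormalized 2-D Gaussian centered on the
# cell's block, then block-average. Mirrors the documented PSF definition
# (Gaussian pre-filter composed with block mean) without separability.
naive_gaussian_degrade <- function(v, s, sigma_out) {
  sig <- sigma_out * s
  r <- ceiling(3 * sig)
  nr <- nrow(v); nc <- ncol(v)
  blurred <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; wt <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        w <- exp(-(di^2 + dj^2) / (2 * sig^2))
        acc <- acc + w * v[ii, jj]; wt <- wt + w
      }
    }
    blurred[i, j] <- acc / wt
  }
  out <- matrix(0, nr / s, nc / s)
  for (i in seq_len(nr / s)) for (j in seq_len(nc / s))
    out[i, j] <- mean(blurred[((i - 1) * s + 1):(i * s),
                              ((j - 1) * s + 1):(j * s)])
  out
}

# Random unit-norm dictionary.
random_dictionary <- function(q, m) {
  D <- matrix(stats::rnorm(q * m), q, m)
  sweep(D, 2, sqrt(colSums(D^2)), "/")
}

# Small valid band with reproducible values.
make_band <- function(nr = 8, nc = nr, band = "nir", pixel_size = 30,
                      seed = 1) {
  set.seed(seed)
  raster_band(matrix(stats::runif(nr * nc, 0.05, 0.95), nr, nc),
              pixel_size = pixel_size, band = band)
}

# Coincident (lr, hr) band pairs for n synthetic dates, one band.
synthetic_pairs <- function(band, n = 3, hr = 64L, seed = 1, ...) {
  lapply(seq_len(n), function(i) {
    sc <- generate_scene_pair(scene_spec(hr_shape = c(hr, hr), s = 2L,
                                         seed = seed * 101 + i, ...))
    list(lr = sc$lr_sensor$bands[[band]], hr = sc$hr_sensor$bands[[band]])
  })
}
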