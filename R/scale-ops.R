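# Scale-change operators: block aggregation (the sensor's coarsening) and
# interpolation upscaling (the smooth baseline I_s), plus the residual field
# the downscaler reconstructs. Coordinate convention throughout: 0-based,
# row-major, half-open windows; LR cell (i,j) covers the HR block
# [s*i, s*i+s) x [s*j, s*j+s).

# Sum of f x f blocks of a matrix (dims must be divisible by f).
block_sum <- function(m, f) {
  nr <- nrow(m); nc <- ncol(m)
  s1 <- colSums(array(m, dim = c(f, nr %/% f, nc)))      # (nr/f) x nc
  t(colSums(array(t(s1), dim = c(f, nc %/% f, nr %/% f))))
}

#' Aggregate a band by block mean
#'
#' Coarsens a band by an integer factor: each output cell is the mean of the
#' valid cells in its `factor` x `factor` block. This is the ideal-box model
#' of a coarse sensor's point spread function; a Gaussian PSF variant is
#' available through [degrade()].
#'
#' @param band A [raster_band()].
#' @param factor Integer aggregation factor, at least 2.
#' @param min_valid_fraction Minimum fraction of valid cells a block needs
#'   for its output cell to be valid; blocks below it are masked. Default 1
#'   (any nodata contaminates the block), the pessimistic choice.
#' @return A [raster_band()] with dimensions divided by `factor` and
#'   `pixel_size` multiplied by `factor`. If the input dimensions are not
#'   divisible by `factor`, trailing rows/columns are cropped with a warning.
#' @seealso [interpolate_upscale()] for the inverse direction.
#' @export
block_aggregate <- function(band, factor, min_valid_fraction = 1) {
  stopifnot_band(band)
  if (length(factor) != 1L || !is.finite(factor) || factor != round(factor) ||
      factor < 2)
    stop("`factor` must be a single integer >= 2", call. = FALSE)
  factor <- as.integer(factor)
  if (length(min_valid_fraction) != 1L || !is.finite(min_valid_fraction) ||
      min_valid_fraction <= 0 || min_valid_fraction > 1)
    stop("`min_valid_fraction` must lie in (0, 1]", call. = FALSE)
  v <- band$values; msk <- band$mask
  nr <- nrow(v) %/% factor * factor
  nc <- ncol(v) %/% factor * factor
  if (nr < factor || nc < factor)
    stop(sprintf("band (%d x %d) smaller than one %d x %d block",
                 nrow(v), ncol(v), factor, factor), call. = FALSE)
  if (nr != nrow(v) || nc != ncol(v)) {
    warning(sprintf(
      "dimensions (%d x %d) not divisible by %d: cropping to %d x %d",
      nrow(v), ncol(v), factor, nr, nc), call. = FALSE)
    v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
    msk <- msk[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  v0 <- v; v0[msk] <- 0
  counts <- block_sum((!msk) * 1, factor)
  sums <- block_sum(v0, factor)
  out <- sums / counts
  out_mask <- counts < min_valid_fraction * factor^2 - 1e-9 | counts == 0
  out[out_mask] <- NA_real_
  raster_band(out, out_mask, pixel_size = band$pixel_size * factor,
              band = band$band)
}

# Row-interpolation weight matrix W (s*n x n) mapping n input samples to s*n
# output samples with cell-center alignment: output index i (0-based) sits at
# input coordinate u = (i + 0.5)/s - 0.5. Out-of-range taps are clamped to
# the edge sample. Rows sum to 1.
upscale_weights <- function(n, s, kernel) {
  i <- seq_len(s * n) - 1L
  u <- (i + 0.5) / s - 0.5
  w <- matrix(0, nrow = s * n, ncol = n)
  clamp_idx <- function(j) pmin(pmax(j, 0L), n - 1L)
  add <- function(j, wt) {
    jj <- clamp_idx(j)
    idx <- cbind(seq_along(u), jj + 1L)
    w[idx] <<- w[idx] + wt
  }
  if (kernel == "nearest") {
    add(as.integer(floor(u + 0.5)), rep(1, length(u)))
  } else if (kernel == "bilinear") {
    j0 <- as.integer(floor(u)); t <- u - j0
    add(j0, 1 - t)
    add(j0 + 1L, t)
  } else if (kernel == "bicubic") {
    # Keys cubic-convolution kernel, a = -0.5
    a <- -0.5
    keys <- function(x) {
      x <- abs(x)
      ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
             ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
    }
    j0 <- as.integer(floor(u)); t <- u - j0
    for (d in -1:2) add(j0 + d, keys(t - d))
  } else {
    stop(sprintf("unknown kernel '%s'; valid kernels: %s", kernel,
                 paste(c("nearest", "bilinear", "bicubic"), collapse = ", ")),
         call. = FALSE)
  }
  w
}

#' Upscale a band to a finer grid by interpolation
#'
#' The smooth interpolation operator: resamples an m x n band onto the
#' (s*m) x (s*n) grid with cell-center alignment. This is the baseline the
#' sparse-coding downscaler improves upon, and the operator used to form the
#' residual field.
#'
#' Nodata propagation is pessimistic: an output cell is masked as soon as any
#' input cell with nonzero kernel weight is masked.
#'
#' @param band A [raster_band()].
#' @param s Integer scale factor, at least 2.
#' @param kernel One of `"nearest"`, `"bilinear"`, `"bicubic"` (Keys cubic
#'   convolution, a = -0.5; the default smooth baseline).
#' @return A [raster_band()] of shape `s * dim(band$values)` with
#'   `pixel_size / s`.
#' @export
interpolate_upscale <- function(band, s, kernel = "bicubic") {
  stopifnot_band(band)
  if (length(s) != 1L || !is.finite(s) || s != round(s) || s < 2)
    stop("`s` must be a single integer >= 2", call. = FALSE)
  s <- as.integer(s)
  if (!is.character(kernel) || length(kernel) != 1L)
    stop("`kernel` must be a single string", call. = FALSE)
  wr <- upscale_weights(nrow(band$values), s, kernel)
  wc <- upscale_weights(ncol(band$values), s, kernel)
  v0 <- band$values; v0[band$mask] <- 0
  out <- wr %*% v0 %*% t(wc)
  touched <- (wr != 0) %*% band$mask %*% t(wc != 0)
  out_mask <- touched > 0
  out[out_mask] <- NA_real_
  raster_band(out, out_mask, pixel_size = band$pixel_size / s,
              band = band$band)
}

#' Residual field between a fine band and an upscaled coarse band
#'
#' The high-frequency content the coarse sensor cannot resolve: the
#' difference between the fine-resolution band and the coarse band
#' interpolated onto the fine grid. This is the quantity the coupled
#' dictionaries are trained to reconstruct.
#'
#' @param hr Fine-resolution [raster_band()], shape `s` times `lr`'s.
#' @param lr Coarse-resolution [raster_band()], same band label.
#' @param s Integer scale factor linking the two grids.
#' @param kernel Interpolation kernel for the upscaling; see
#'   [interpolate_upscale()].
#' @return A [raster_band()] on the fine grid, masked wherever either input
#'   (after upscaling) is masked.
#' @export
residual_field <- function(hr, lr, s, kernel = "bicubic") {
  stopifnot_band(hr); stopifnot_band(lr)
  if (!identical(hr$band, lr$band))
    stop(sprintf("band labels differ: hr '%s' vs lr '%s'", hr$band, lr$band),
         call. = FALSE)
  if (length(s) != 1L || !is.finite(s) || s != round(s) || s < 2)
    stop("`s` must be a single integer >= 2", call. = FALSE)
  s <- as.integer(s)
  if (!identical(dim(hr$values), s * dim(lr$values)))
    stop(sprintf(
      "shape mismatch: hr is %d x %d but lr is %d x %d with s = %d (expected %d x %d)",
      nrow(hr$values), ncol(hr$values), nrow(lr$values), ncol(lr$values), s,
      s * nrow(lr$values), s * ncol(lr$values)), call. = FALSE)
  up <- interpolate_upscale(lr, s, kernel)
  out_mask <- hr$mask | up$mask
  out <- hr$values - up$values
  out[out_mask] <- NA_real_
  raster_band(out, out_mask, pixel_size = hr$pixel_size, band = hr$band)
}
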