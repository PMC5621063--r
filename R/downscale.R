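#' Downscaling configuration
#'
#' Bundles the tunable parameters of the sparse-coding downscaler.
#'
#' @param s Integer scale factor (2 and 4 are the intended settings).
#' @param patch_edge Coarse patch edge p (cells).
#' @param stride Reconstruction stride in \[1, p\]; 1 (maximal overlap, the
#'   blocking-artifact remedy) by default, `p` for non-overlapping speed.
#' @param k_max,tol Pursuit stopping parameters; see [omp()]. The default
#'   of a single atom per patch is deliberately conservative: with small
#'   raw-intensity patches, deeper pursuits fit coarse-grid sensor noise
#'   and transfer unrelated fine-scale texture from the dictionary, which
#'   hurts out-of-dictionary reconstruction (see the methods vignette).
#' @param kernel Interpolation kernel for the smooth baseline.
#' @param seed Optional integer seed recorded for any randomized choices
#'   (the pipeline itself is deterministic).
#' @return An object of class `downscale_config`.
#' @export
downscale_config <- function(s = 2L, patch_edge = 3L, stride = 1L,
                             k_max = 1L, tol = 1e-3, kernel = "bicubic",
                             seed = NULL) {
  s <- as.integer(s); p <- as.integer(patch_edge); st <- as.integer(stride)
  if (is.na(s) || s < 2L) stop("`s` must be an integer >= 2", call. = FALSE)
  if (is.na(p) || p < 1L) stop("`patch_edge` must be >= 1", call. = FALSE)
  if (is.na(st) || st < 1L || st > p)
    stop("`stride` must lie in [1, patch_edge]", call. = FALSE)
  if (k_max < 0L) stop("`k_max` must be >= 0", call. = FALSE)
  if (tol < 0) stop("`tol` must be >= 0", call. = FALSE)
  structure(list(s = s, patch_edge = p, stride = st,
                 k_max = as.integer(k_max), tol = tol, kernel = kernel,
                 seed = seed),
            class = "downscale_config")
}

#' Downscale one band with a coupled dictionary
#'
#' The core reconstruction: the coarse band is (1) upscaled to the fine grid
#' by interpolation, then (2) tiled into patches, each of which is scaled to
#' unit norm and sparse-coded against the low-resolution dictionary by
#' [omp()]; (3) the same coefficients combine the matching high-resolution
#' residual atoms (undoing the unit-norm scaling of both query and atoms)
#' into a fine-grid residual patch; (4) residual patches are re-assembled by
#' overlap averaging and added to the interpolated baseline. The low- and
#' high-resolution fields are assumed geometrically similar, which is what
#' licenses reusing the coarse-patch coefficients on the fine atoms.
#'
#' Zero-norm query patches skip coding and contribute a zero residual, so
#' `k_max = 0` reduces the pipeline exactly to plain interpolation.
#'
#' @param lr Coarse [raster_band()] to sharpen.
#' @param dict A [build_coupled_dictionary()] result matching the band and
#'   the configured `s` and `patch_edge`.
#' @param cfg A [downscale_config()].
#' @return A fine-grid [raster_band()] of shape `s * dim(lr)`, masked where
#'   the interpolated baseline is masked.
#' @export
downscale_band <- function(lr, dict, cfg = downscale_config()) {
  stopifnot_band(lr)
  if (!inherits(dict, "coupled_dictionary"))
    stop("`dict` must be a coupled_dictionary", call. = FALSE)
  if (!inherits(cfg, "downscale_config"))
    stop("`cfg` must be a downscale_config", call. = FALSE)
  if (!identical(dict$band, lr$band))
    stop(sprintf("dictionary is for band '%s' but input is '%s'",
                 dict$band, lr$band), call. = FALSE)
  if (dict$s != cfg$s || dict$patch_edge != cfg$patch_edge)
    stop(sprintf(
      "dictionary (s = %d, p = %d) does not match config (s = %d, p = %d)",
      dict$s, dict$patch_edge, cfg$s, cfg$patch_edge), call. = FALSE)
  if (!ncol(dict$D_l)) stop("dictionary is empty", call. = FALSE)

  s <- cfg$s; p <- cfg$patch_edge; hp <- s * p
  base <- interpolate_upscale(lr, s, cfg$kernel)
  patches <- extract_patches(lr, p, cfg$stride, drop_masked = TRUE)
  synth <- .omp_synthesize_cpp(patches$vectors, dict$D_l, dict$D_h,
                               dict$atom_norms, cfg$k_max, cfg$tol,
                               TRUE, dict$center)
  resid_vecs <- synth$residuals
  rp <- structure(list(vectors = resid_vecs, patch_edge = hp,
                       stride = s * cfg$stride, origins = patches$origins * s,
                       source_shape = s * patches$source_shape),
                  class = "patch_set")
  xr <- assemble_patches(rp, target_shape = dim(base$values),
                         pixel_size = base$pixel_size, band = lr$band)
  rv <- xr$values
  rv[xr$mask] <- 0                      # uncovered cells: no residual
  out <- base$values + rv
  out[base$mask] <- NA_real_
  # residual patches are ~zero-mean by construction; a large drift of the
  # output mean against the interpolated baseline hints at a mismatched
  # dictionary and is reported (not fatal)
  mb <- mean(base$values[!base$mask]); mo <- mean(out[!base$mask])
  if (is.finite(mb) && abs(mb) > 1e-12 && abs(mo - mb) > 0.02 * abs(mb))
    message(sprintf(
      "downscale_band(%s): output mean %.5g drifts %.1f%% from baseline mean %.5g",
      lr$band, mo, 100 * abs(mo - mb) / abs(mb), mb))
  res <- raster_band(out, base$mask, pixel_size = base$pixel_size,
                     band = lr$band)
  attr(res, "coding_stats") <- list(
    n_patches = ncol(patches$vectors),
    mean_sparsity = mean(synth$n_atoms),
    residual_rms = sqrt(mean(rv[!base$mask]^2)))
  log_stage("downscale_band", sprintf(
    "band=%s patches=%d mean_sparsity=%.2f residual_rms=%.4g",
    lr$band, ncol(patches$vectors), mean(synth$n_atoms),
    sqrt(mean(rv[!base$mask]^2))))
  res
}

#' Downscale every band of a scene
#'
#' Applies [downscale_band()] independently per band.
#'
#' @param x Coarse [scene()].
#' @param dicts Named list of [build_coupled_dictionary()] objects, keyed by
#'   band label.
#' @param cfg A [downscale_config()].
#' @param bands Bands to process; defaults to all bands of the scene.
#' @return A fine-grid [scene()] tagged `"downscaled"`.
#' @export
downscale_scene <- function(x, dicts, cfg = downscale_config(),
                            bands = names(x$bands)) {
  if (!inherits(x, "scene")) stop("`x` must be a scene", call. = FALSE)
  missing <- setdiff(bands, names(x$bands))
  if (length(missing))
    stop(sprintf("scene lacks band(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  nodict <- setdiff(bands, names(dicts))
  if (length(nodict))
    stop(sprintf("no dictionary for band(s): %s",
                 paste(nodict, collapse = ", ")), call. = FALSE)
  out <- lapply(bands, function(nm)
    downscale_band(x$bands[[nm]], dicts[[nm]], cfg))
  names(out) <- bands
  scene(out, acquired = x$acquired, platform = "downscaled")
}
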