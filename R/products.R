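#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), the standard greenness index in
#' \[-1, 1\]. Cells where either input is masked, or where the denominator
#' is at or below `epsilon` (guarding the division), are masked.
#'
#' @param red,nir Co-gridded [raster_band()]s.
#' @param epsilon Denominator guard; default 1e-9.
#' @return A [raster_band()] that also carries class `index_band`, with
#'   band label `"ndvi"`.
#' @examples
#' r <- raster_band(matrix(0.1, 2, 2), band = "red")
#' n <- raster_band(matrix(0.5, 2, 2), band = "nir")
#' ndvi(r, n)$values[1, 1]   # 0.4 / 0.6
#' @export
ndvi <- function(red, nir, epsilon = 1e-9) {
  stopifnot_band(red); stopifnot_band(nir)
  if (!identical(dim(red$values), dim(nir$values)))
    stop(sprintf("shape mismatch: red %d x %d vs nir %d x %d",
                 nrow(red$values), ncol(red$values),
                 nrow(nir$values), ncol(nir$values)), call. = FALSE)
  denom <- nir$values + red$values
  msk <- red$mask | nir$mask
  msk <- msk | is.na(denom) | denom <= epsilon
  v <- (nir$values - red$values) / denom
  v[msk] <- NA_real_
  out <- raster_band(v, msk, pixel_size = red$pixel_size, band = "ndvi")
  class(out) <- c("index_band", class(out))
  out
}
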