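#' Band labels understood by the package
#'
#' The five spectral channels handled by the downscaling pipeline. The
#' `thermal` band carries brightness temperature in kelvin; all others carry
#' surface reflectance (unitless, nominally in \[0, 1\]). Derived index
#' layers (e.g. `"ndvi"`) use their own labels.
#' @export
BAND_LABELS <- c("red", "green", "blue", "nir", "thermal")

#' Create a raster band
#'
#' The package's basic data container: a 2-D grid of physical values
#' (reflectance or brightness temperature) together with a nodata mask, the
#' ground sample distance, and a band label. Masked cells are stored as `NA`
#' and are excluded from every statistic and every patch.
#'
#' @param values Numeric matrix of cell values. `NA`/`NaN` cells are treated
#'   as nodata.
#' @param mask Optional logical matrix, same shape, `TRUE` where the cell is
#'   nodata. Merged with non-finite cells of `values`.
#' @param pixel_size Ground sample distance in meters (single positive
#'   number).
#' @param band Band label; one of [BAND_LABELS] or a derived-index name.
#' @return An object of class `raster_band` with fields `values`, `mask`,
#'   `pixel_size`, `band`.
#' @examples
#' b <- raster_band(matrix(runif(16), 4, 4), pixel_size = 30, band = "nir")
#' b
#' @export
raster_band <- function(values, mask = NULL, pixel_size = 1, band = "red") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must have at least one cell", call. = FALSE)
  storage.mode(values) <- "double"
  if (is.null(mask)) {
    mask <- !is.finite(values)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(values)))
      stop("`mask` must be a logical matrix with the same shape as `values`",
           call. = FALSE)
    mask <- mask | !is.finite(values)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  if (!is.character(band) || length(band) != 1L)
    stop("`band` must be a single character label", call. = FALSE)
  values[mask] <- NA_real_
  structure(
    list(values = values, mask = mask,
         pixel_size = as.numeric(pixel_size), band = band),
    class = "raster_band"
  )
}

#' @export
print.raster_band <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf("<raster_band> %s: %d x %d cells, pixel %g m, %d masked\n",
              x$band, nrow(x$values), ncol(x$values),
              x$pixel_size, sum(x$mask)))
  if (length(v))
    cat(sprintf("  range [%.6g, %.6g], mean %.6g\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

is_raster_band <- function(x) inherits(x, "raster_band")

stopifnot_band <- function(x, arg = deparse(substitute(x))) {
  if (!is_raster_band(x))
    stop(sprintf("`%s` must be a raster_band", arg), call. = FALSE)
  invisible(x)
}

#' Check that a reflectance band is radiometrically plausible
#'
#' Verifies that valid cells of a reflectance band lie within \[0, 1\] up to
#' a tolerance. Thermal and derived-index bands are not checked.
#'
#' @param band A [raster_band()].
#' @param tol Allowed excursion beyond \[0, 1\].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_reflectance <- function(band, tol = 1e-6) {
  stopifnot_band(band)
  if (band$band %in% c("red", "green", "blue", "nir")) {
    v <- band$values[!band$mask]
    if (length(v) && (min(v) < -tol || max(v) > 1 + tol))
      stop(sprintf("band '%s' has reflectance outside [0, 1] (range [%g, %g])",
                   band$band, min(v), max(v)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Create a multi-band scene
#'
#' A set of co-registered bands on one common grid, acquired together from a
#' single platform.
#'
#' @param bands Named list of [raster_band()] objects, all with identical
#'   shape and pixel size. Names must equal each band's own label.
#' @param acquired Optional acquisition date (anything coercible by
#'   [as.Date()]), or `NULL`.
#' @param platform Free-text platform tag (e.g. `"coarse-sensor"`).
#' @return An object of class `scene`.
#' @export
scene <- function(bands, acquired = NULL, platform = "") {
  if (!is.list(bands) || length(bands) == 0L || is.null(names(bands)) ||
      any(!nzchar(names(bands))))
    stop("`bands` must be a non-empty named list of raster_band objects",
         call. = FALSE)
  for (nm in names(bands)) {
    stopifnot_band(bands[[nm]], nm)
    if (!identical(bands[[nm]]$band, nm))
      stop(sprintf("list name '%s' does not match band label '%s'",
                   nm, bands[[nm]]$band), call. = FALSE)
  }
  shp <- dim(bands[[1L]]$values)
  px <- bands[[1L]]$pixel_size
  for (b in bands) {
    if (!identical(dim(b$values), shp) || !isTRUE(all.equal(b$pixel_size, px)))
      stop("all bands of a scene must share shape and pixel_size",
           call. = FALSE)
  }
  if (!is.null(acquired)) acquired <- as.Date(acquired)
  structure(list(bands = bands, acquired = acquired, platform = platform),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s: %s | %d x %d cells, pixel %g m | bands: %s\n",
              if (nzchar(x$platform)) x$platform else "(untagged)",
              if (is.null(x$acquired)) "undated" else format(x$acquired),
              nrow(x$bands[[1L]]$values), ncol(x$bands[[1L]]$values),
              x$bands[[1L]]$pixel_size,
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}
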