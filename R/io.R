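# Raster file I/O. The payload is a single-sample TIFF; georeferencing
# metadata (pixel size, band label, nodata value and the affine value
# scaling) travels in a JSON sidecar `<file>.aux.json`, since plain TIFF
# carries no geotransform. TIFF samples are stored scaled to [0, 1] at
# 32-bit depth, so values round-trip to about 2^-32 of the value range;
# masked cells are stored at the nodata value and recovered by equality
# against it, the usual nodata-tag semantics.

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a raster band to a TIFF file with a JSON sidecar
#'
#' @param band A [raster_band()].
#' @param path Output file path (conventionally `.tif`). A sidecar
#'   `<path>.aux.json` is written next to it.
#' @param nodata Physical value used to encode masked cells. Must not fall
#'   inside the valid-value range; the default sits just below the data
#'   minimum, which keeps the stored value scaling (and hence the
#'   quantization step) tight.
#' @return `path`, invisibly.
#' @seealso [read_band()]
#' @export
write_band <- function(band, path, nodata = NULL) {
  stopifnot_band(band)
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write '%s': directory '%s' does not exist",
                 path, dirname(path)), call. = FALSE)
  v <- band$values
  valid <- v[!band$mask]
  vr <- if (length(valid)) range(valid) else c(0, 1)
  if (is.null(nodata))
    nodata <- vr[1L] - 0.05 * (diff(vr) + 1)
  if (length(valid) && nodata >= vr[1L] && nodata <= vr[2L])
    stop("`nodata` value falls inside the data range", call. = FALSE)
  lo <- min(vr[1L], nodata); hi <- max(vr[2L], nodata)
  if (hi <= lo) hi <- lo + 1
  v[band$mask] <- nodata
  tiff::writeTIFF((v - lo) / (hi - lo), path, bits.per.sample = 32L,
                  compression = "deflate")
  meta <- list(format = "patchscale-raster-1",
               pixel_size = band$pixel_size, band = band$band,
               nodata = nodata, scale_min = lo, scale_max = hi)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster band from a TIFF file with a JSON sidecar
#'
#' Reads a band written by [write_band()] (or any single/multi-sample TIFF
#' accompanied by a compatible sidecar). Cells equal to the sidecar's nodata
#' value are masked.
#'
#' @param path Path to the TIFF file.
#' @param band Optional band label override; defaults to the sidecar's.
#' @param index 1-based sample index for multi-sample files.
#' @return A [raster_band()].
#' @export
read_band <- function(path, band = NULL, index = 1L) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf(
      "'%s' has no georeferencing sidecar ('%s' missing): pixel size unknown",
      path, sc), call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("pixel_size", "nodata", "scale_min", "scale_max"))
    if (is.null(meta[[f]]))
      stop(sprintf("sidecar '%s' lacks required field '%s'", sc, f),
           call. = FALSE)
  raw <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(raw)) == 3L) {
    if (index < 1L || index > dim(raw)[3L])
      stop(sprintf("band index %d out of range: '%s' has %d band(s)",
                   index, path, dim(raw)[3L]), call. = FALSE)
    raw <- raw[, , index]
  } else if (index != 1L) {
    stop(sprintf("band index %d out of range: '%s' has 1 band", index, path),
         call. = FALSE)
  }
  v <- meta$scale_min + raw * (meta$scale_max - meta$scale_min)
  tol <- 1e-6 * max(meta$scale_max - meta$scale_min, 1e-12)
  msk <- abs(v - meta$nodata) <= tol
  v[msk] <- NA_real_
  raster_band(v, msk, pixel_size = meta$pixel_size,
              band = if (is.null(band)) meta$band else band)
}

#' Write all bands of a scene to a directory
#'
#' One `<band>.tif` file (plus sidecar) per band, and a `scene.json` with
#' the acquisition date and platform tag.
#'
#' @param x A [scene()].
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(x, dir) {
  if (!inherits(x, "scene")) stop("`x` must be a scene", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(x$bands))
    write_band(x$bands[[nm]], file.path(dir, paste0(nm, ".tif")))
  jsonlite::write_json(
    list(format = "patchscale-scene-1",
         acquired = if (is.null(x$acquired)) NULL else format(x$acquired),
         platform = x$platform, bands = names(x$bands)),
    file.path(dir, "scene.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir Scene directory.
#' @param bands Optional subset of band labels to read.
#' @return A [scene()].
#' @export
read_scene <- function(dir, bands = NULL) {
  mf <- file.path(dir, "scene.json")
  if (!file.exists(mf))
    stop(sprintf("'%s' is not a scene directory (no scene.json)", dir),
         call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  want <- if (is.null(bands)) meta$bands else bands
  missing <- setdiff(want, meta$bands)
  if (length(missing))
    stop(sprintf("scene '%s' lacks band(s): %s", dir,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bl <- lapply(want, function(nm)
    read_band(file.path(dir, paste0(nm, ".tif"))))
  names(bl) <- want
  scene(bl,
        acquired = if (is.null(meta$acquired) || is.na(meta$acquired[1L]))
          NULL else meta$acquired,
        platform = if (is.null(meta$platform)) "" else meta$platform)
}
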