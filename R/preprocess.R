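# Radiometric homogenization between platforms: histogram matching with the
# coarse sensor as the bias-free baseline. The mapping is a monotone
# piecewise-linear transform between matched empirical quantiles, estimated
# at the aggregated (common-grid) scale and applicable at native scale.

#' Estimate a histogram-matching mapping between two bands
#'
#' Matches the empirical distribution of `source` to that of `reference` by
#' pairing quantiles at `n_quantiles` evenly spaced probability levels
#' (valid cells only). The coarse-platform band is normally the reference.
#'
#' @param source [raster_band()] whose values are to be corrected.
#' @param reference [raster_band()] providing the target distribution; same
#'   band label.
#' @param n_quantiles Number of probability levels (>= 2); 256 by default.
#' @return An object of class `monotone_mapping` with fields
#'   `source_quantiles`, `reference_quantiles`, `band`.
#' @seealso [apply_mapping()], [write_mapping()]
#' @export
estimate_histogram_mapping <- function(source, reference,
                                       n_quantiles = 256L) {
  stopifnot_band(source); stopifnot_band(reference)
  if (!identical(source$band, reference$band))
    stop(sprintf("band labels differ: '%s' vs '%s'",
                 source$band, reference$band), call. = FALSE)
  n_quantiles <- as.integer(n_quantiles)
  if (is.na(n_quantiles) || n_quantiles < 2L)
    stop("`n_quantiles` must be an integer >= 2", call. = FALSE)
  sv <- source$values[!source$mask]
  rv <- reference$values[!reference$mask]
  if (length(sv) < n_quantiles || length(rv) < n_quantiles)
    stop(sprintf(
      "need at least %d valid cells in each band (source has %d, reference %d)",
      n_quantiles, length(sv), length(rv)), call. = FALSE)
  probs <- seq(0, 1, length.out = n_quantiles)
  structure(list(
    source_quantiles = unname(stats::quantile(sv, probs, type = 7)),
    reference_quantiles = unname(stats::quantile(rv, probs, type = 7)),
    band = source$band),
    class = "monotone_mapping")
}

#' @export
print.monotone_mapping <- function(x, ...) {
  cat(sprintf(
    "<monotone_mapping> band %s: %d knots, [%.4g, %.4g] -> [%.4g, %.4g]\n",
    x$band, length(x$source_quantiles),
    min(x$source_quantiles), max(x$source_quantiles),
    min(x$reference_quantiles), max(x$reference_quantiles)))
  invisible(x)
}

# Monotone piecewise-linear evaluation with linear extrapolation from the
# end segments. Duplicate source knots are collapsed (mean of their
# reference values, which preserves monotonicity on sorted inputs).
map_values <- function(x, sq, rq) {
  keep_rq <- as.numeric(tapply(rq, match(sq, unique(sq)), mean))
  keep_sq <- unique(sq)
  k <- length(keep_sq)
  if (k == 1L)                 # degenerate constant source: unit slope
    return(keep_rq[1L] + (x - keep_sq[1L]))
  out <- stats::approx(keep_sq, keep_rq, xout = x, rule = 2)$y
  lo_sl <- (keep_rq[2L] - keep_rq[1L]) / (keep_sq[2L] - keep_sq[1L])
  hi_sl <- (keep_rq[k] - keep_rq[k - 1L]) / (keep_sq[k] - keep_sq[k - 1L])
  below <- !is.na(x) & x < keep_sq[1L]
  above <- !is.na(x) & x > keep_sq[k]
  out[below] <- keep_rq[1L] + lo_sl * (x[below] - keep_sq[1L])
  out[above] <- keep_rq[k] + hi_sl * (x[above] - keep_sq[k])
  out
}

#' Apply a histogram-matching mapping to a band
#'
#' Transforms each valid cell by piecewise-linear interpolation between the
#' mapping's quantile pairs; values beyond the observed source range are
#' extrapolated linearly from the end segments (no clamping, which would
#' pile mass into histogram spikes). The mask is unchanged. A mapping
#' estimated at the aggregated scale may be applied at native fine
#' resolution.
#'
#' @param band [raster_band()] with the mapping's band label.
#' @param mapping A [estimate_histogram_mapping()] result.
#' @return The transformed [raster_band()].
#' @export
apply_mapping <- function(band, mapping) {
  stopifnot_band(band)
  if (!inherits(mapping, "monotone_mapping"))
    stop("`mapping` must be a monotone_mapping", call. = FALSE)
  if (!identical(band$band, mapping$band))
    stop(sprintf("band '%s' does not match mapping band '%s'",
                 band$band, mapping$band), call. = FALSE)
  v <- band$values
  ok <- !band$mask
  v[ok] <- map_values(v[ok], mapping$source_quantiles,
                      mapping$reference_quantiles)
  raster_band(v, band$mask, pixel_size = band$pixel_size, band = band$band)
}

#' Save / load a histogram mapping as a two-column text table
#'
#' Tab-separated columns `source_quantile`, `reference_quantile`, for audit
#' and reuse.
#'
#' @param mapping A `monotone_mapping`.
#' @param path Text file path.
#' @param band Band label to attach when reading.
#' @return `path` invisibly, or the mapping.
#' @export
write_mapping <- function(mapping, path) {
  if (!inherits(mapping, "monotone_mapping"))
    stop("`mapping` must be a monotone_mapping", call. = FALSE)
  utils::write.table(
    data.frame(source_quantile = mapping$source_quantiles,
               reference_quantile = mapping$reference_quantiles,
               band = mapping$band),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path, band = NULL) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE)
  structure(list(source_quantiles = tb$source_quantile,
                 reference_quantiles = tb$reference_quantile,
                 band = if (is.null(band)) as.character(tb$band[1L]) else band),
            class = "monotone_mapping")
}
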