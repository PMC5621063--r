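# Seeded generator of coincident coarse/fine multi-band scenes over
# center-pivot agricultural fields. The generated ensembles give the
# downscaler something real imagery would: disk-shaped vegetated fields
# with sharp boundaries, band-coupled high-frequency texture present only
# at the fine scale, sensor noise, and an optional gain/offset bias on the
# fine platform.

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable Gaussian blur with boundary renormalization (weights of
# out-of-bounds taps are redistributed, so constants stay constant).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  blur1 <- function(x) {           # along rows (first margin)
    n <- nrow(x)
    acc <- matrix(0, n, ncol(x)); wt <- matrix(0, n, ncol(x))
    for (d in -r:r) {
      src <- (1:n) + d
      ok <- src >= 1L & src <= n
      w <- k[d + r + 1L]
      acc[ok, ] <- acc[ok, ] + w * x[src[ok], , drop = FALSE]
      wt[ok, ] <- wt[ok, ] + w
    }
    acc / wt
  }
  t(blur1(t(blur1(m))))
}

# Per-band radiometry: background (bare-soil) reflectance level, response
# of the band inside a vegetated pivot disk, and the gain applied to the
# shared high-frequency texture field. Levels follow typical dry-soil vs
# dense-crop spectra: chlorophyll absorption darkens all visible bands over
# vegetation (red most strongly) while the NIR plateau brightens it, and
# transpiring canopy is cooler than bare soil. Thermal is in kelvin.
band_radiometry <- function() {
  list(
    red     = list(base = 0.20, bg_amp = 0.030, pivot = -0.150, tex = 1.0),
    green   = list(base = 0.16, bg_amp = 0.025, pivot = -0.070, tex = 1.0),
    blue    = list(base = 0.11, bg_amp = 0.020, pivot = -0.070, tex = 0.8),
    nir     = list(base = 0.28, bg_amp = 0.040, pivot = +0.200, tex = 1.6),
    thermal = list(base = 308,  bg_amp = 2.0,   pivot = -8.0,   tex = 30)
  )
}

#' Specification of a synthetic paired scene
#'
#' Parameters of the generator. Defaults describe a desk-scale analog of an
#' irrigated center-pivot study area: a 128 x 128 fine grid two-fold finer
#' than the coarse grid, three pivot disks, 3% high-frequency reflectance
#' texture with a 2-cell correlation length, 0.2% sensor noise, and an
#' unbiased fine platform.
#'
#' @param hr_shape Fine-grid dimensions `c(rows, cols)`; must be divisible
#'   by `s`.
#' @param s Integer scale factor between the fine and coarse grids.
#' @param n_pivots Number of circular vegetated fields.
#' @param texture_amplitude Standard deviation of the high-frequency
#'   texture, in reflectance units (scaled per band; see Details).
#' @param texture_correlation Spatial correlation length of the texture in
#'   fine-grid cells (Gaussian smoothing sigma).
#' @param bias `c(gain, offset)` applied to the fine platform's measurement
#'   to emulate inter-sensor radiometric bias.
#' @param noise_sd Additive sensor noise standard deviation in reflectance
#'   units (scaled by 50 for the thermal band's kelvin range).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `scene_spec`.
#' @details One texture field is generated at the fine scale and shared
#'   across bands with band-specific gains, so the bands are geometrically
#'   similar — the structural assumption the coupled-dictionary transfer of
#'   coefficients relies on.
#' @export
scene_spec <- function(hr_shape = c(128L, 128L), s = 2L, n_pivots = 3L,
                       texture_amplitude = 0.03, texture_correlation = 2,
                       bias = c(gain = 1, offset = 0), noise_sd = 0.002,
                       seed = 1L) {
  hr_shape <- as.integer(hr_shape); s <- as.integer(s)
  if (length(hr_shape) != 2L || any(is.na(hr_shape)) || any(hr_shape < s))
    stop("`hr_shape` must be two positive integers", call. = FALSE)
  if (is.na(s) || s < 2L) stop("`s` must be an integer >= 2", call. = FALSE)
  if (any(hr_shape %% s != 0L))
    stop("`hr_shape` must be divisible by `s`", call. = FALSE)
  if (n_pivots < 0L) stop("`n_pivots` must be >= 0", call. = FALSE)
  if (texture_amplitude < 0 || texture_correlation < 0 || noise_sd < 0)
    stop("amplitudes and correlation length must be >= 0", call. = FALSE)
  if (length(bias) != 2L || any(!is.finite(bias)))
    stop("`bias` must be c(gain, offset)", call. = FALSE)
  structure(list(hr_shape = hr_shape, s = s, n_pivots = as.integer(n_pivots),
                 texture_amplitude = texture_amplitude,
                 texture_correlation = texture_correlation,
                 bias = c(gain = unname(bias[1L]), offset = unname(bias[2L])),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a coincident coarse/fine synthetic scene pair
#'
#' Builds a latent five-band reflectance/temperature field (smooth
#' background + pivot disks + shared fine-scale texture), then observes it
#' with two emulated platforms: the coarse sensor (block aggregation of the
#' truth plus noise; the bias-free baseline) and the fine sensor (the truth
#' under a gain/offset bias plus noise). Same seed, same output,
#' bit-identically.
#'
#' @param spec A [scene_spec()].
#' @return List with elements `hr_true`, `hr_sensor`, `lr_sensor`
#'   ([scene()]s; the coarse scene has pixel size 30 m, the fine scenes
#'   `30/s` m) and `pivots`, a data frame of disk centers/radii (fine-grid
#'   units) for ground-truth checks. The fraction of fine-sensor cells
#'   clipped to the physical range is attached as attribute
#'   `clip_fraction`.
#' @export
generate_scene_pair <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    stop("`spec` must be a scene_spec", call. = FALSE)
  nr <- spec$hr_shape[1L]; nc <- spec$hr_shape[2L]; s <- spec$s
  rad <- band_radiometry()
  with_seed(spec$seed, {
    # smooth background: coarse white noise, bicubically upscaled
    f <- 8L
    cb <- matrix(stats::rnorm(ceiling(nr / f) * ceiling(nc / f)),
                 ceiling(nr / f), ceiling(nc / f))
    bg <- interpolate_upscale(raster_band(cb, band = "red"), f,
                              "bicubic")$values[1:nr, 1:nc]
    # pivot disks
    pivots <- data.frame(row = numeric(0), col = numeric(0),
                         radius = numeric(0))
    inside <- matrix(FALSE, nr, nc)
    if (spec$n_pivots > 0L) {
      pivots <- data.frame(
        row = stats::runif(spec$n_pivots, 0.2 * nr, 0.8 * nr),
        col = stats::runif(spec$n_pivots, 0.2 * nc, 0.8 * nc),
        radius = stats::runif(spec$n_pivots, 0.10, 0.18) * min(nr, nc))
      rr <- row(inside); cc <- col(inside)
      for (i in seq_len(spec$n_pivots))
        inside <- inside | (rr - pivots$row[i])^2 + (cc - pivots$col[i])^2 <=
          pivots$radius[i]^2
    }
    # shared fine-scale texture, unit variance, zero mean
    tex <- matrix(0, nr, nc)
    if (spec$texture_amplitude > 0) {
      tex <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc),
                           spec$texture_correlation)
      tex <- (tex - mean(tex)) / stats::sd(tex)
    }
    lims <- function(nm) if (nm == "thermal") c(250, 350) else c(0, 1)
    truth <- list(); hr_obs <- list(); lr_obs <- list()
    clipped <- 0; total <- 0
    for (nm in BAND_LABELS) {
      pb <- rad[[nm]]
      v <- pb$base + pb$bg_amp * bg + pb$pivot * inside +
        pb$tex * spec$texture_amplitude * tex
      v <- clamp(v, lims(nm)[1L], lims(nm)[2L])
      truth[[nm]] <- raster_band(v, pixel_size = 30 / s, band = nm)
      nsd <- spec$noise_sd * if (nm == "thermal") 50 else 1
      lv <- block_aggregate(truth[[nm]], s)$values +
        matrix(stats::rnorm((nr / s) * (nc / s), sd = nsd), nr / s, nc / s)
      lr_obs[[nm]] <- raster_band(lv, pixel_size = 30, band = nm)
      hv <- spec$bias[["gain"]] * v + spec$bias[["offset"]] +
        matrix(stats::rnorm(nr * nc, sd = nsd), nr, nc)
      hv_cl <- clamp(hv, lims(nm)[1L], lims(nm)[2L])
      clipped <- clipped + sum(hv_cl != hv); total <- total + length(hv)
      hr_obs[[nm]] <- raster_band(hv_cl, pixel_size = 30 / s, band = nm)
    }
    out <- list(
      hr_true = scene(truth, platform = "truth"),
      hr_sensor = scene(hr_obs, platform = "fine-sensor"),
      lr_sensor = scene(lr_obs, platform = "coarse-sensor"),
      pivots = pivots)
    attr(out, "clip_fraction") <- clipped / total
    out
  })
}

#' Degrade a fine band to a coarse grid through a sensor PSF
#'
#' Simulates a coarse sensor observing a fine field: the band is convolved
#' with the point spread function, reduced by block mean to the coarse
#' grid, and optionally perturbed with additive Gaussian noise. The `box`
#' PSF is the pure block mean ([block_aggregate()]); the `gaussian` PSF
#' composes a Gaussian pre-filter (boundary-renormalized, sigma expressed
#' in output-pixel units) with the block mean.
#'
#' @param hr Fine [raster_band()], dimensions divisible by `s`.
#' @param s Integer reduction factor.
#' @param psf `"box"` or `"gaussian"`.
#' @param noise_sd Additive noise standard deviation (0 for none).
#' @param seed Seed for the noise draw; required when `noise_sd > 0`.
#' @param sigma Gaussian PSF sigma in output-pixel units (default 0.5).
#' @return A coarse [raster_band()].
#' @export
degrade <- function(hr, s, psf = c("box", "gaussian"), noise_sd = 0,
                    seed = NULL, sigma = 0.5) {
  stopifnot_band(hr)
  psf <- match.arg(psf)
  if (any(dim(hr$values) %% s != 0L))
    stop("`hr` dimensions must be divisible by `s`", call. = FALSE)
  src <- hr
  if (psf == "gaussian") {
    if (any(hr$mask))
      stop("gaussian PSF degradation requires a fully valid band",
           call. = FALSE)
    src <- raster_band(gaussian_blur(hr$values, sigma * s),
                       pixel_size = hr$pixel_size, band = hr$band)
  }
  out <- block_aggregate(src, s)
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("`seed` is required when `noise_sd` > 0", call. = FALSE)
    nz <- with_seed(seed,
      matrix(stats::rnorm(length(out$values), sd = noise_sd),
             nrow(out$values)))
    out <- raster_band(out$values + nz, out$mask,
                       pixel_size = out$pixel_size, band = out$band)
  }
  out
}
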