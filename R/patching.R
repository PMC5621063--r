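# Patch machinery: extraction into vectorized columns, overlap-averaged
# re-assembly, and construction of the coupled LR/HR-residual dictionaries.

# Patch origins along one axis (0-based): multiples of `stride`, plus a
# final right-aligned origin so every cell is covered.
axis_origins <- function(n, p, stride) {
  o <- seq.int(0L, n - p, by = stride)
  if (o[length(o)] != n - p) o <- c(o, n - p)
  as.integer(o)
}

# Flat (column-major, 1-based) cell indices of one patch per column, for
# patches of edge p at the given 0-based (row, col) origins. Within a patch,
# cells are ordered row-major: (0,0), (0,1), ..., (1,0), ...
patch_index_matrix <- function(nr, origins, p) {
  dr <- rep(0:(p - 1L), each = p)
  dc <- rep(0:(p - 1L), p)
  rel <- dr + dc * nr
  org <- origins[, 1L] + origins[, 2L] * nr
  outer(rel, org, "+") + 1L
}

#' Extract vectorized patches from a band
#'
#' Tiles the band with square patches of edge `patch_edge` at origins that
#' are multiples of `stride` (row-major order), adding right/bottom-aligned
#' origins so that every cell is covered. Each patch is vectorized row-major
#' into one column.
#'
#' @param band A [raster_band()].
#' @param patch_edge Patch edge length p in cells (>= 1).
#' @param stride Offset between successive patch origins (>= 1).
#' @param drop_masked If `TRUE`, patches containing any masked cell are
#'   omitted (the origin list records the survivors).
#' @return An object of class `patch_set`: list with `vectors` (p^2 x N
#'   matrix), `patch_edge`, `stride`, `origins` (N x 2 matrix of 0-based
#'   (row, col) origins), `source_shape`.
#' @seealso [assemble_patches()]
#' @export
extract_patches <- function(band, patch_edge, stride = 1L,
                            drop_masked = FALSE) {
  stopifnot_band(band)
  p <- as.integer(patch_edge); st <- as.integer(stride)
  nr <- nrow(band$values); nc <- ncol(band$values)
  if (is.na(p) || p < 1L) stop("`patch_edge` must be >= 1", call. = FALSE)
  if (is.na(st) || st < 1L) stop("`stride` must be >= 1", call. = FALSE)
  if (p > nr || p > nc)
    stop(sprintf("patch_edge %d exceeds image dimensions (%d x %d)",
                 p, nr, nc), call. = FALSE)
  ro <- axis_origins(nr, p, st); co <- axis_origins(nc, p, st)
  origins <- cbind(rep(ro, each = length(co)), rep(co, length(ro)))
  idx <- patch_index_matrix(nr, origins, p)
  vecs <- matrix(band$values[idx], nrow = p * p)
  if (drop_masked) {
    keep <- colSums(matrix(band$mask[idx], nrow = p * p)) == 0L
    vecs <- vecs[, keep, drop = FALSE]
    origins <- origins[keep, , drop = FALSE]
  }
  structure(list(vectors = vecs, patch_edge = p, stride = st,
                 origins = origins, source_shape = c(nr, nc)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d cells (stride %d) from a %d x %d image\n",
              ncol(x$vectors), x$patch_edge, x$patch_edge, x$stride,
              x$source_shape[1L], x$source_shape[2L]))
  invisible(x)
}

#' Re-assemble patches into a band by overlap averaging
#'
#' Inverse of [extract_patches()]: each output cell is the unweighted mean
#' of all patch values covering it. Cells covered by no patch (and `NA`
#' patch entries) contribute nothing and are masked.
#'
#' @param patches A `patch_set`.
#' @param target_shape Integer vector `c(rows, cols)` of the output grid;
#'   defaults to the patch set's `source_shape`.
#' @param pixel_size,band Metadata for the output [raster_band()].
#' @return A [raster_band()].
#' @export
assemble_patches <- function(patches, target_shape = patches$source_shape,
                             pixel_size = 1, band = "red") {
  if (!inherits(patches, "patch_set"))
    stop("`patches` must be a patch_set", call. = FALSE)
  p <- patches$patch_edge
  nr <- as.integer(target_shape[1L]); nc <- as.integer(target_shape[2L])
  org <- patches$origins
  n <- ncol(patches$vectors)
  if (nrow(org) != n || nrow(patches$vectors) != p * p)
    stop("patch set geometry is inconsistent", call. = FALSE)
  if (n && (max(org[, 1L]) + p > nr || max(org[, 2L]) + p > nc ||
            min(org) < 0L))
    stop(sprintf("patch origins do not fit a %d x %d target", nr, nc),
         call. = FALSE)
  sums <- matrix(0, nr, nc); counts <- matrix(0, nr, nc)
  if (n) {
    idx <- patch_index_matrix(nr, org, p)
    for (j in seq_len(n)) {
      v <- patches$vectors[, j]
      ok <- !is.na(v)
      ix <- idx[ok, j]
      sums[ix] <- sums[ix] + v[ok]
      counts[ix] <- counts[ix] + 1
    }
  }
  out <- sums / counts
  msk <- counts == 0
  out[msk] <- NA_real_
  raster_band(out, msk, pixel_size = pixel_size, band = band)
}

#' Build a coupled low/high-resolution patch dictionary
#'
#' Collects matched training examples from coincident coarse/fine image
#' pairs: for each pair the fine band is reduced to its residual field (fine
#' minus interpolated coarse), coarse patches of edge `patch_edge` are
#' paired with the residual patches of edge `s * patch_edge` covering the
#' same ground footprint, and the vectorized pairs become the columns of the
#' low-resolution dictionary `D_l` (q x M, q = patch_edge^2) and the
#' high-resolution dictionary `D_h` (s^2 q x M). `D_l` columns are stored
#' with unit Euclidean norm; the original norms are kept in `atom_norms`.
#'
#' Pairs whose coarse or fine patch touches a masked cell are dropped, as
#' are zero-norm coarse patches.
#'
#' @param pairs List of `list(lr = , hr = )` pairs of [raster_band()]s; all
#'   on the same band, with `dim(hr) == s * dim(lr)`.
#' @param s Integer scale factor.
#' @param patch_edge Coarse patch edge p (the fine patch edge is `s * p`).
#' @param stride Training stride on the coarse grid; 1 (maximal overlap) by
#'   default.
#' @param kernel Interpolation kernel used to form the residual fields.
#' @param residual If `FALSE`, store raw fine-band patches in `D_h` instead
#'   of residual patches.
#' @param center If `TRUE`, remove each coarse patch's mean before
#'   normalization (recorded in the dictionary and replayed at coding time).
#' @return An object of class `coupled_dictionary`.
#' @export
build_coupled_dictionary <- function(pairs, s, patch_edge = 3L, stride = 1L,
                                     kernel = "bicubic", residual = TRUE,
                                     center = FALSE) {
  if (!is.list(pairs) || !length(pairs))
    stop("`pairs` must be a non-empty list of (lr, hr) pairs", call. = FALSE)
  s <- as.integer(s); p <- as.integer(patch_edge)
  band_label <- NULL
  dl <- list(); dh <- list()
  for (pr in pairs) {
    lr <- pr$lr; hr <- pr$hr
    stopifnot_band(lr, "lr"); stopifnot_band(hr, "hr")
    if (is.null(band_label)) band_label <- lr$band
    if (!identical(lr$band, band_label) || !identical(hr$band, band_label))
      stop(sprintf("mixed bands in training pairs ('%s' vs '%s')",
                   band_label, lr$band), call. = FALSE)
    target <- if (residual) residual_field(hr, lr, s, kernel) else hr
    lp <- extract_patches(lr, p, stride, drop_masked = FALSE)
    # matching fine patches: edge s*p at origins s*(r, c)
    hidx <- patch_index_matrix(nrow(target$values),
                               lp$origins * s, s * p)
    hvec <- matrix(target$values[hidx], nrow = (s * p)^2)
    ok <- colSums(is.na(lp$vectors)) == 0L & colSums(is.na(hvec)) == 0L
    dl[[length(dl) + 1L]] <- lp$vectors[, ok, drop = FALSE]
    dh[[length(dh) + 1L]] <- hvec[, ok, drop = FALSE]
  }
  d_l <- do.call(cbind, dl); d_h <- do.call(cbind, dh)
  if (center && ncol(d_l))
    d_l <- sweep(d_l, 2L, colMeans(d_l))
  norms <- sqrt(colSums(d_l^2))
  keep <- norms > 1e-12
  d_l <- d_l[, keep, drop = FALSE]; d_h <- d_h[, keep, drop = FALSE]
  norms <- norms[keep]
  if (!ncol(d_l))
    stop(paste("no valid training patch pairs survived filtering;",
               "reduce `stride`/`patch_edge` or provide less-masked pairs"),
         call. = FALSE)
  d_l <- sweep(d_l, 2L, norms, "/")
  structure(list(D_l = d_l, D_h = d_h, s = s, patch_edge = p,
                 band = band_label, atom_norms = norms, lr_kernel = kernel,
                 residual = residual, center = center,
                 n_pairs = length(pairs)),
            class = "coupled_dictionary")
}

#' @export
print.coupled_dictionary <- function(x, ...) {
  cat(sprintf(
    "<coupled_dictionary> band %s: M = %d atoms from %d pair(s), s = %d, p = %d (%s D_h, %s kernel)\n",
    x$band, ncol(x$D_l), x$n_pairs, x$s, x$patch_edge,
    if (x$residual) "residual" else "raw-HR", x$lr_kernel))
  invisible(x)
}

#' Save / load a coupled dictionary
#'
#' A dictionary is a plain self-contained archive (both matrices plus all
#' metadata) written with [saveRDS()].
#'
#' @param dict A `coupled_dictionary`.
#' @param path Archive file path.
#' @return `path` invisibly (`write_dictionary`) or the dictionary
#'   (`read_dictionary`).
#' @export
write_dictionary <- function(dict, path) {
  if (!inherits(dict, "coupled_dictionary"))
    stop("`dict` must be a coupled_dictionary", call. = FALSE)
  saveRDS(dict, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  d <- readRDS(path)
  if (!inherits(d, "coupled_dictionary"))
    stop(sprintf("'%s' does not contain a coupled_dictionary", path),
         call. = FALSE)
  d
}
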