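#' Orthogonal matching pursuit
#'
#' Greedy sparse approximation of a signal over a dictionary with unit-norm
#' columns. At each iteration the atom with the largest absolute inner
#' product with the current estimation residual is added to the support
#' (ties broken toward the lowest atom index), all coefficients on the
#' support are refit by ordinary least squares, and the residual is updated.
#' Iterations stop when the residual norm falls below the threshold or
#' `k_max` atoms have been selected.
#'
#' If the support submatrix becomes numerically rank-deficient the last
#' selection is rolled back and the pursuit stops with a warning rather than
#' failing.
#'
#' @param y Numeric signal vector of length q.
#' @param D q x M numeric dictionary; columns must have unit Euclidean norm
#'   (within 1e-9) unless `normalize = TRUE`.
#' @param k_max Maximum number of atoms (0 yields an empty code). Must not
#'   exceed `min(q, M)`.
#' @param tol Stopping threshold on the residual norm; relative to
#'   `norm(y)` when `relative = TRUE` (the default), absolute otherwise.
#' @param relative Interpret `tol` relative to the signal norm?
#' @param normalize Normalize dictionary columns on entry instead of
#'   erroring on non-unit norms (coefficients then refer to the normalized
#'   atoms).
#' @return An object of class `sparse_code`: `support` (1-based atom
#'   indices in order of selection), `coefficients` (least-squares values
#'   aligned to the support), `residual_norm`, `n_iterations`, and
#'   `residual_trace` (norms after each iteration, starting at
#'   `norm(y)`).
#' @examples
#' D <- qr.Q(qr(matrix(rnorm(36), 6)))   # orthonormal atoms
#' omp(2 * D[, 3], D, k_max = 2)
#' @export
omp <- function(y, D, k_max = 8L, tol = 1e-3, relative = TRUE,
                normalize = FALSE) {
  if (!is.numeric(y)) stop("`y` must be numeric", call. = FALSE)
  y <- as.numeric(y)
  if (!is.matrix(D) || !is.numeric(D))
    stop("`D` must be a numeric matrix", call. = FALSE)
  q <- nrow(D); m <- ncol(D)
  if (length(y) != q)
    stop(sprintf("length(y) = %d does not match nrow(D) = %d",
                 length(y), q), call. = FALSE)
  norms <- sqrt(colSums(D^2))
  if (normalize) {
    if (any(norms <= 1e-12))
      stop("`D` contains zero-norm columns", call. = FALSE)
    D <- sweep(D, 2L, norms, "/")
  } else if (any(abs(norms - 1) > 1e-9)) {
    stop(paste("dictionary columns are not unit-norm;",
               "pass `normalize = TRUE` to normalize on entry"),
         call. = FALSE)
  }
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 0L)
    stop("`k_max` must be a non-negative integer", call. = FALSE)
  if (k_max > min(q, m))
    stop(sprintf("k_max = %d exceeds min(q, M) = %d", k_max, min(q, m)),
         call. = FALSE)
  if (tol < 0) stop("`tol` must be >= 0", call. = FALSE)

  ny <- sqrt(sum(y^2))
  res <- .omp_cpp(y, D, k_max, if (relative) tol * ny else tol)
  structure(list(support = as.integer(res$support),
                 coefficients = as.numeric(res$coefficients),
                 residual_norm = res$residual_norm,
                 n_iterations = length(res$support),
                 residual_trace = as.numeric(res$residual_trace)),
            class = "sparse_code")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code> %d atom(s), residual norm %.3g\n",
              x$n_iterations, x$residual_norm))
  if (x$n_iterations)
    cat("  support:", paste(x$support, collapse = ", "),
        "\n  coefficients:", paste(signif(x$coefficients, 4), collapse = ", "),
        "\n")
  invisible(x)
}
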