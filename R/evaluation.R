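# Quantitative scoring of downscaled products against an aggregated
# high-resolution benchmark: RMSE and the relative RMSE reduction
# ("improvement ratio") versus the interpolation-only baseline.

#' Root mean square error between two co-gridded bands
#'
#' Computed over jointly valid cells only.
#'
#' @param a,b [raster_band()]s with identical shape.
#' @return A single non-negative number.
#' @export
rmse <- function(a, b) {
  stopifnot_band(a); stopifnot_band(b)
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("shape mismatch: %d x %d vs %d x %d",
                 nrow(a$values), ncol(a$values),
                 nrow(b$values), ncol(b$values)), call. = FALSE)
  ok <- !(a$mask | b$mask)
  if (!any(ok))
    stop("no jointly valid cells to compare", call. = FALSE)
  sqrt(mean((a$values[ok] - b$values[ok])^2))
}

#' Score a downscaled band against a high-resolution benchmark
#'
#' Computes the RMSE of the downscaled band and of the interpolation-only
#' baseline (both against the benchmark, which the caller prepares on the
#' downscaled grid, typically by [block_aggregate()]ing finer imagery), and
#' the improvement ratio
#' `100 * (1 - rmse_downscaled / rmse_baseline)` — the percent relative
#' RMSE reduction, 0 meaning no gain over interpolation and 100 meaning an
#' exact match to the benchmark.
#'
#' @param downscaled Fine-grid [raster_band()] produced by
#'   [downscale_band()].
#' @param lr The coarse input band it was produced from.
#' @param benchmark_hr Benchmark [raster_band()] on the downscaled grid.
#' @param s Scale factor between `lr` and the fine grid.
#' @param kernel Interpolation kernel defining the baseline.
#' @param scenario Optional scenario tag (1 = benchmark pair in the
#'   training set, 2 = left out) recorded in the report.
#' @return An object of class `eval_report`: `rmse_downscaled`,
#'   `rmse_baseline`, `improvement_ratio` (percent), `n_cells`, `band`,
#'   `s`, `scenario`, and `pairs`, a data frame of (downscaled, benchmark)
#'   cell samples for scatter plots.
#' @export
evaluate_downscaling <- function(downscaled, lr, benchmark_hr, s,
                                 kernel = "bicubic", scenario = NA) {
  baseline <- interpolate_upscale(lr, s, kernel)
  eval_against_baseline(downscaled, baseline, benchmark_hr,
                        s = s, scenario = scenario)
}

# Shared core, also used for products (e.g. NDVI) whose baseline is not a
# direct interpolation of one coarse band.
eval_against_baseline <- function(downscaled, baseline, benchmark_hr,
                                  s = NA, scenario = NA) {
  stopifnot_band(downscaled); stopifnot_band(benchmark_hr)
  if (!identical(dim(downscaled$values), dim(benchmark_hr$values)))
    stop(sprintf("grid mismatch: downscaled %d x %d vs benchmark %d x %d",
                 nrow(downscaled$values), ncol(downscaled$values),
                 nrow(benchmark_hr$values), ncol(benchmark_hr$values)),
         call. = FALSE)
  r_d <- rmse(downscaled, benchmark_hr)
  r_b <- rmse(baseline, benchmark_hr)
  ok <- !(downscaled$mask | benchmark_hr$mask)
  structure(list(
    rmse_downscaled = r_d,
    rmse_baseline = r_b,
    improvement_ratio = if (r_b > 0) 100 * (1 - r_d / r_b) else NA_real_,
    n_cells = sum(ok),
    band = downscaled$band, s = s, scenario = scenario,
    pairs = data.frame(downscaled = downscaled$values[ok],
                       benchmark = benchmark_hr$values[ok])),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> band %s (s = %s%s): RMSE %.5g vs baseline %.5g -> improvement %.2f%% (n = %d)\n",
    x$band, as.character(x$s),
    if (is.na(x$scenario)) "" else paste0(", scenario ", x$scenario),
    x$rmse_downscaled, x$rmse_baseline, x$improvement_ratio, x$n_cells))
  invisible(x)
}

#' Write an evaluation report to JSON (and optionally its scatter samples)
#'
#' @param report An `eval_report`.
#' @param path JSON output path.
#' @param scatter Optional CSV path for the paired (downscaled, benchmark)
#'   cell samples.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, scatter = NULL) {
  if (!inherits(report, "eval_report"))
    stop("`report` must be an eval_report", call. = FALSE)
  jsonlite::write_json(
    report[c("rmse_downscaled", "rmse_baseline", "improvement_ratio",
             "n_cells", "band", "s", "scenario")],
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(scatter))
    utils::write.csv(report$pairs, scatter, row.names = FALSE)
  invisible(path)
}
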