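# Configuration-driven orchestration of the full experiment:
# debias -> train dictionaries -> downscale -> derive NDVI -> evaluate,
# under scenario 1 (every pair in the dictionary) or scenario 2
# (leave-one-out validation).

config_error <- function(msg)
  stop(structure(class = c("patchscale_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))

#' Experiment configuration
#'
#' @param pairs List of `list(lr = , hr = , date = )` entries. `lr` and
#'   `hr` may be [scene()] objects or paths to scene directories written by
#'   [write_scene()]; `date` is a unique tag.
#' @param scenario 1 (all pairs train the dictionary; every date is
#'   evaluated) or 2 (the `held_out` date is excluded from training and is
#'   the only one evaluated).
#' @param held_out Date tag to hold out (scenario 2; ignored otherwise).
#' @param bands Band labels to process.
#' @param downscale A [downscale_config()].
#' @param debias Apply histogram-matching bias correction to the fine
#'   scenes, with the coarse platform as baseline?
#' @param n_quantiles Quantile levels for the bias correction.
#' @param outputs Optional directory for intermediate rasters and the
#'   summary JSON; `NULL` keeps everything in memory.
#' @param evaluate_dates Optional subset of date tags to evaluate
#'   (defaults to the scenario's rule).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(pairs, scenario = 1L, held_out = NULL,
                              bands = BAND_LABELS,
                              downscale = downscale_config(),
                              debias = TRUE, n_quantiles = 256L,
                              outputs = NULL, evaluate_dates = NULL) {
  if (!is.list(pairs) || !length(pairs))
    config_error("`pairs` must be a non-empty list")
  dates <- vapply(pairs, function(p) as.character(p$date), "")
  if (anyDuplicated(dates) || any(!nzchar(dates)))
    config_error("each pair needs a unique non-empty `date` tag")
  if (!scenario %in% c(1L, 2L))
    config_error("`scenario` must be 1 or 2")
  if (scenario == 2L) {
    if (is.null(held_out) || !held_out %in% dates)
      config_error(sprintf(
        "scenario 2 requires `held_out` to name one of the pairs (%s)",
        paste(dates, collapse = ", ")))
  }
  if (!inherits(downscale, "downscale_config"))
    config_error("`downscale` must be a downscale_config")
  if (!is.null(evaluate_dates) && !all(evaluate_dates %in% dates))
    config_error("`evaluate_dates` must be a subset of the pair dates")
  structure(list(pairs = pairs, dates = dates, scenario = as.integer(scenario),
                 held_out = held_out, bands = bands, downscale = downscale,
                 debias = isTRUE(debias), n_quantiles = as.integer(n_quantiles),
                 outputs = outputs, evaluate_dates = evaluate_dates),
            class = "experiment_config")
}

load_scene_input <- function(x, bands) {
  if (inherits(x, "scene")) x else read_scene(x, bands = bands)
}

#' Run a full downscaling experiment
#'
#' Per band: (a) aggregate each fine scene to the coarse grid, estimate the
#' histogram mapping against its coarse scene, and apply it to the fine
#' scene at native scale (when `debias` is on); (b) aggregate the
#' (debiased) fine scenes down to the target fine grid — the coarse grid
#' times the configured scale factor — to form benchmarks; (c) build the
#' coupled dictionary from the scenario's training pairs; (d) downscale
#' each evaluated coarse scene; (e) derive NDVI from the downscaled red and
#' NIR bands; (f) score every product against its benchmark. Results are
#' keyed `"band:date"`.
#'
#' @param cfg An [experiment_config()].
#' @return List with `reports` (named list of [evaluate_downscaling()]
#'   reports, including `ndvi` entries when red and nir are processed),
#'   `summary` (one data frame row per report), and `downscaled` (named
#'   list of downscaled [scene()]s per evaluated date). If `cfg$outputs`
#'   is set, downscaled bands and `summary.json` are written there.
#' @export
run_experiment <- function(cfg) {
  if (!inherits(cfg, "experiment_config"))
    config_error("`cfg` must be an experiment_config")
  s <- cfg$downscale$s
  kern <- cfg$downscale$kernel
  bands <- cfg$bands
  lrs <- lapply(cfg$pairs, function(p) load_scene_input(p$lr, bands))
  hrs <- lapply(cfg$pairs, function(p) load_scene_input(p$hr, bands))
  names(lrs) <- names(hrs) <- cfg$dates

  d0 <- dim(lrs[[1L]]$bands[[1L]]$values)
  dh <- dim(hrs[[1L]]$bands[[1L]]$values)
  f_native <- unique(dh / d0)
  if (length(f_native) != 1L || f_native != round(f_native))
    stop("fine scenes must be an integer multiple of the coarse grid",
         call. = FALSE)
  f_bench <- f_native / s
  if (f_bench != round(f_bench) || f_bench < 1)
    stop(sprintf(
      "fine grid (factor %d) cannot be aggregated to the target grid (s = %d)",
      f_native, s), call. = FALSE)

  train_dates <- if (cfg$scenario == 1L) cfg$dates
                 else setdiff(cfg$dates, cfg$held_out)
  eval_dates <- if (!is.null(cfg$evaluate_dates)) cfg$evaluate_dates
                else if (cfg$scenario == 1L) cfg$dates
                else cfg$held_out

  # (a) debias + (b) benchmarks on the target fine grid
  benchmarks <- list()
  for (d in cfg$dates) {
    bb <- list()
    for (nm in bands) {
      hb <- hrs[[d]]$bands[[nm]]
      if (cfg$debias) {
        agg <- block_aggregate(hb, f_native)
        mp <- estimate_histogram_mapping(agg, lrs[[d]]$bands[[nm]],
                                         cfg$n_quantiles)
        hb <- apply_mapping(hb, mp)
      }
      bb[[nm]] <- if (f_bench > 1) block_aggregate(hb, f_bench) else hb
    }
    benchmarks[[d]] <- bb
    log_stage("benchmark", sprintf(
      "date=%s debias=%s cells=%d", d, cfg$debias,
      length(bb[[1L]]$values)))
  }

  # (c) per-band dictionaries from the training pairs
  dicts <- lapply(bands, function(nm)
    build_coupled_dictionary(
      lapply(train_dates, function(d)
        list(lr = lrs[[d]]$bands[[nm]], hr = benchmarks[[d]][[nm]])),
      s = s, patch_edge = cfg$downscale$patch_edge,
      stride = cfg$downscale$stride, kernel = kern))
  names(dicts) <- bands
  log_stage("train", sprintf(
    "dates=%s atoms=%s", paste(train_dates, collapse = "+"),
    paste(vapply(dicts, function(d) ncol(d$D_l), 0L), collapse = "/")))

  # (d)-(f) downscale, derive, evaluate
  reports <- list()
  downscaled <- list()
  for (d in eval_dates) {
    t0 <- Sys.time()
    ds <- downscale_scene(lrs[[d]], dicts, cfg$downscale, bands = bands)
    log_stage("downscale", sprintf(
      "date=%s bands=%d elapsed=%.2fs", d, length(bands),
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    downscaled[[d]] <- ds
    for (nm in bands)
      reports[[paste(nm, d, sep = ":")]] <-
        evaluate_downscaling(ds$bands[[nm]], lrs[[d]]$bands[[nm]],
                             benchmarks[[d]][[nm]], s, kern,
                             scenario = cfg$scenario)
    if (all(c("red", "nir") %in% bands)) {
      nd_ds <- ndvi(ds$bands$red, ds$bands$nir)
      nd_bm <- ndvi(benchmarks[[d]]$red, benchmarks[[d]]$nir)
      nd_bl <- ndvi(interpolate_upscale(lrs[[d]]$bands$red, s, kern),
                    interpolate_upscale(lrs[[d]]$bands$nir, s, kern))
      reports[[paste("ndvi", d, sep = ":")]] <-
        eval_against_baseline(nd_ds, nd_bl, nd_bm, s = s,
                              scenario = cfg$scenario)
    }
  }

  summary_df <- do.call(rbind, lapply(names(reports), function(k) {
    r <- reports[[k]]
    data.frame(band = r$band, date = sub("^[^:]*:", "", k),
               scenario = r$scenario, s = r$s,
               rmse_downscaled = r$rmse_downscaled,
               rmse_baseline = r$rmse_baseline,
               improvement_ratio = r$improvement_ratio,
               n_cells = r$n_cells)
  }))

  if (!is.null(cfg$outputs)) {
    dir.create(cfg$outputs, recursive = TRUE, showWarnings = FALSE)
    for (d in names(downscaled))
      write_scene(downscaled[[d]],
                  file.path(cfg$outputs, paste0("downscaled_", d)))
    jsonlite::write_json(summary_df, file.path(cfg$outputs, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(reports = reports, summary = summary_df, downscaled = downscaled)
}

#' Read an experiment configuration from a YAML file
#'
#' The YAML mirrors [experiment_config()]: a `pairs` list of
#' `{lr: <scene dir>, hr: <scene dir>, date: <tag>}` entries, `scenario`,
#' `held_out`, `bands`, `debias`, `n_quantiles`, `outputs`, and a
#' `downscale` block with any of `s`, `patch_edge`, `stride`, `k_max`,
#' `tol`, `kernel`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path))
    config_error(sprintf("config file '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$pairs)) config_error("config lacks a `pairs` list")
  ds <- do.call(downscale_config, c(list(), y$downscale))
  experiment_config(
    pairs = y$pairs,
    scenario = if (is.null(y$scenario)) 1L else y$scenario,
    held_out = y$held_out,
    bands = if (is.null(y$bands)) BAND_LABELS else unlist(y$bands),
    downscale = ds,
    debias = if (is.null(y$debias)) TRUE else y$debias,
    n_quantiles = if (is.null(y$n_quantiles)) 256L else y$n_quantiles,
    outputs = y$outputs,
    evaluate_dates = if (is.null(y$evaluate_dates)) NULL
                     else unlist(y$evaluate_dates))
}
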