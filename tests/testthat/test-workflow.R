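make_pairs <- function(n = 3, hr = 32L, seed = 500, ...) {
  lapply(seq_len(n), function(i) {
    sc <- generate_scene_pair(scene_spec(hr_shape = c(hr, hr), s = 2L,
                                         seed = seed + i, ...))
    list(lr = sc$lr_sensor, hr = sc$hr_sensor, date = paste0("d", i))
  })
}

test_that("experiment_config enforces the scenario contract before any compute", {
  pairs <- make_pairs(2)
  expect_error(experiment_config(pairs, scenario = 2),
               class = "patchscale_config_error")
  expect_error(experiment_config(pairs, scenario = 2, held_out = "nope"),
               class = "patchscale_config_error")
  expect_error(experiment_config(list(), scenario = 1),
               class = "patchscale_config_error")
  dup <- pairs; dup[[2]]$date <- "d1"
  expect_error(experiment_config(dup, scenario = 1),
               class = "patchscale_config_error")
  expect_error(experiment_config(pairs, evaluate_dates = "d9"),
               class = "patchscale_config_error")
  cfg <- experiment_config(pairs, scenario = 2, held_out = "d2")
  expect_s3_class(cfg, "experiment_config")
})

test_that("scenario 1 on a single pair with non-overlapping stride recovers the benchmark", {
  pairs <- make_pairs(1, hr = 32L, seed = 520)
  cfg <- experiment_config(
    pairs, scenario = 1, bands = c("red", "nir"),
    downscale = downscale_config(s = 2, patch_edge = 3, stride = 3,
                                 k_max = 1, tol = 0),
    debias = FALSE)
  res <- run_experiment(cfg)
  band_rows <- res$summary$band %in% c("red", "nir")
  expect_true(all(res$summary$improvement_ratio[band_rows] >= 99.9))
})

test_that("run_experiment evaluates only the held-out date under scenario 2", {
  pairs <- make_pairs(3, hr = 32L, seed = 530)
  cfg <- experiment_config(
    pairs, scenario = 2, held_out = "d2", bands = c("red", "nir"),
    downscale = downscale_config(s = 2, k_max = 1), debias = FALSE,
    n_quantiles = 64)
  res <- run_experiment(cfg)
  expect_setequal(unique(res$summary$date), "d2")
  expect_setequal(res$summary$band, c("red", "nir", "ndvi"))
  expect_true(all(res$summary$n_cells > 0))
  expect_named(res$downscaled, "d2")
})

test_that("run_experiment is bit-reproducible and writes its outputs", {
  pairs <- make_pairs(2, hr = 32L, seed = 540)
  outdir <- withr::local_tempdir()
  cfg <- experiment_config(
    pairs, scenario = 1, bands = c("red", "nir"),
    downscale = downscale_config(s = 2, k_max = 1), debias = TRUE,
    n_quantiles = 64, outputs = outdir)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$downscaled$d1$bands$nir$values,
                   r2$downscaled$d1$bands$nir$values)
  expect_true(file.exists(file.path(outdir, "summary.json")))
  expect_true(file.exists(file.path(outdir, "downscaled_d1", "nir.tif")))
  back <- read_scene(file.path(outdir, "downscaled_d2"))
  expect_equal(back$bands$red$values, r1$downscaled$d2$bands$red$values,
               tolerance = 1e-7)
})

test_that("run_experiment accepts scene directories as inputs", {
  pairs <- make_pairs(1, hr = 32L, seed = 550)
  d_lr <- withr::local_tempdir(); d_hr <- withr::local_tempdir()
  write_scene(pairs[[1]]$lr, d_lr)
  write_scene(pairs[[1]]$hr, d_hr)
  cfg <- experiment_config(
    list(list(lr = d_lr, hr = d_hr, date = "d1")), scenario = 1,
    bands = "nir", downscale = downscale_config(s = 2, k_max = 1),
    debias = FALSE)
  res <- run_experiment(cfg)
  expect_equal(nrow(res$summary), 1L)
  expect_gt(res$summary$improvement_ratio, -100)
})

test_that("experiment configs load from YAML", {
  pairs <- make_pairs(2, hr = 32L, seed = 560)
  d1l <- withr::local_tempdir(); d1h <- withr::local_tempdir()
  d2l <- withr::local_tempdir(); d2h <- withr::local_tempdir()
  write_scene(pairs[[1]]$lr, d1l); write_scene(pairs[[1]]$hr, d1h)
  write_scene(pairs[[2]]$lr, d2l); write_scene(pairs[[2]]$hr, d2h)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(sprintf(
    "pairs:
  - {lr: %s, hr: %s, date: d1}
  - {lr: %s, hr: %s, date: d2}
scenario: 2
held_out: d2
bands: [red, nir]
debias: false
downscale: {s: 2, k_max: 1, stride: 2}
", d1l, d1h, d2l, d2h), yml)
  cfg <- read_experiment_config(yml)
  expect_s3_class(cfg, "experiment_config")
  expect_identical(cfg$held_out, "d2")
  expect_equal(cfg$downscale$stride, 2L)
  res <- run_experiment(cfg)
  expect_setequal(res$summary$band, c("red", "nir", "ndvi"))
  expect_error(read_experiment_config("/nonexistent.yaml"),
               class = "patchscale_config_error")
})
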