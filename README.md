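# patchscale

Patch-based statistical downscaling of multispectral imagery for
precision agriculture.

Satellite sensors that revisit a field often enough for management
decisions (e.g. a 30 m multispectral platform) are too coarse to resolve
within-field variability, while aircraft and UAV campaigns that do resolve
it are sporadic. `patchscale` bridges the two: given a few coincident
coarse/fine image pairs over the same fields, it learns how fine-scale
structure relates to its coarse appearance and uses that to sharpen coarse
bands by a factor of 2 or 4 — along with derived products such as NDVI.
The intended users are remote-sensing and agricultural researchers working
with co-registered multi-platform reflectance or brightness-temperature
rasters.

## Method

Let `X_l ∈ R^{m×n}` be a coarse band and `X_h ∈ R^{sm×sn}` its fine
counterpart (scale factor `s ∈ {2, 4}`). With `I_s` a smooth interpolation
operator (bicubic by default), the residual field

    X_r = X_h − I_s(X_l)

holds exactly the high-frequency content the coarse sensor cannot see.
From coincident training pairs, vectorized coarse patches (edge `p`,
default 3) and their matching residual patches (edge `sp`) are collected
column-wise into a coupled pair of dictionaries `D_l ∈ R^{q×M}` and
`D_h ∈ R^{s²q×M}` (`q = p²`), with `D_l` columns stored at unit norm. To
downscale a new coarse band, every patch `y` is sparse-coded against `D_l`
with orthogonal matching pursuit — greedily selecting the atom with the
largest absolute inner product with the current residual and refitting
coefficients by least squares — and, assuming the coarse and fine fields
are geometrically similar, the same coefficients combine the paired `D_h`
atoms into the estimated fine-scale residual patch. Overlap-averaged
residual patches are added to `I_s(X_l)` to form the result.

Around that core the package provides:

- histogram-matching radiometric de-biasing between platforms (monotone
  quantile mapping, coarse sensor as baseline);
- aggregation/interpolation operators with pessimistic nodata handling;
- NDVI derivation and RMSE / improvement-ratio evaluation against an
  aggregated fine-sensor benchmark, where
  `improvement = 100 · (1 − RMSE_downscaled / RMSE_baseline)`;
- a seeded generator of synthetic paired scenes over center-pivot fields,
  so the full experiment design (scenario 1: the evaluated pair is in the
  dictionary; scenario 2: leave-one-out) runs without any downloads;
- a YAML-driven experiment runner and a CLI
  (`inst/cli/patchscale.R {simulate, debias, train-dict, downscale, ndvi,
  evaluate, run}`).

## Worked example

Three synthetic acquisition dates; the dictionary is trained on the first
two and the third is downscaled and scored against its own fine-sensor
benchmark (leave-one-out, scenario 2):

```r
library(patchscale)

pairs <- lapply(1:3, function(i) {
  sc <- generate_scene_pair(scene_spec(seed = 100 + i))
  list(lr = sc$lr_sensor, hr = sc$hr_sensor,
       date = c("jun01", "jun09", "jun17")[i])
})
cfg <- experiment_config(pairs, scenario = 2, held_out = "jun17",
                         bands = c("red", "nir"),
                         downscale = downscale_config(s = 2))
res <- run_experiment(cfg)
res$summary
#>   band  date scenario s rmse_downscaled rmse_baseline improvement_ratio n_cells
#> 1  red jun17        2 2         0.00663       0.00767              13.6   16384
#> 2  nir jun17        2 2         0.00912       0.01019              10.5   16384
#> 3 ndvi jun17        2 2         0.02692       0.03131              14.0   16384
```

Reading the `nir` row: on the 128×128 fine grid the plain bicubic
baseline misses the benchmark by an RMSE of 0.0102 reflectance; the
dictionary reconstruction reduces that to 0.0091, a 10.5% relative RMSE
reduction — structure genuinely recovered from patches learned on *other*
dates. `ndvi` is derived from the downscaled red/NIR bands and scored the
same way.

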