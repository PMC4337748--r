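# rangecover

Animal home-range size analysed against a *continuous* representation of
land cover. Categorical maps force each pixel into one class; `rangecover`
instead models per-pixel **fractional cover** (percent forest / open /
other), summarizes it and its spatial texture inside kernel home ranges at
nested spatio-temporal scales, and explains variation in log home-range
area with a selected linear mixed model. A synthetic-data module generates
landscapes, imagery, terrain and GPS telemetry with known planted effects,
so the whole chain is testable end to end without any external data.

The package is aimed at movement ecologists and landscape-remote-sensing
analysts who want the full pipeline — or any single stage — as plain R
functions with reproducible seeds.

## The methods in brief

* **Fractional cover.** A fine categorical map (e.g. a 5 m photo
  classification regrouped to forest / open / other) is aggregated to
  exact class percentages per 30 m pixel. A random-forest regression
  (1000 trees, `mtry = floor(bands/3)`) maps 5-band pixel spectra to
  percent cover per class, reporting out-of-bag variance explained
  `100 (1 − MSE_OOB / Var y)`; predictions are clipped to [0, 100] and
  rescaled per pixel so the class layers sum to 100.
* **Home ranges.** Fixes thinned to ≥ 1 h spacing, May–September,
  windowed monthly / biweekly / weekly (≥ 10 fixes); fixed-kernel
  utilization distributions with the reference bandwidth
  `h = 0.5 (sd_x + sd_y) n^(-1/6)`; home ranges are the 50 / 70 / 90 %
  isopleths (smallest regions holding that probability mass), areas in
  km².
* **Texture.** Haralick statistics of the forest-fraction layer from the
  3×3-neighbourhood gray-level co-occurrence matrix (16 levels on the
  fixed 0–100 scale, four symmetric directions); headline metric is
  contrast `Σ (i−j)² p(i,j)`, with a buffer-based screen (500–7000 m) that
  ranks metrics by size dependency.
* **Habitat model.** Per home range: mean and SD of forest cover, mean
  contrast, mean elevation; response is ln area (km²). Random-intercept
  structure (individual / sex / year) chosen by REML likelihood-ratio
  tests + AIC; fixed effects (with quadratic texture and elevation)
  reduced by backward elimination under ML at an inclusive |t| ≥ 2; final
  REML refit; per-variable explained deviance by drop-one ML comparisons.

## Worked example

Simulate a 3 × 3 km landscape, learn fractional cover from the synthetic
imagery, track 15 collared animals whose monthly range size follows a
known law (+0.4 per SD of cover variability, −0.35 on squared
standardized texture, individual intercept sd 0.3), and refit that law
from the telemetry alone:

```r
library(rangecover)

cfg <- landscape_config(extent = c(600L, 600L), correlation_length = 120,
                        trend_length = 900, trend_weight = 0.45,
                        grain_lengths = c(25, 150), grain_mix_length = 700,
                        seed = 1)
fine  <- simulate_fine_landcover(cfg)
truth <- aggregate_fractions(fine, cfg$aggregation_factor)
image <- simulate_coarse_image(fine, cfg, spectral_model(noise_sd = 0.01, seed = 2))

fit <- fit_fraction_model(image, truth, ensemble_config(n_trees = 300, seed = 3),
                          target_class = "forest")
print(fit$report)
#> fraction model ('forest'): 300 trees, mtry 1, 10000 pixels
#>   OOB variance explained: 99.48%   OOB RMSE: 3.33% cover

models <- list(forest = fit$model,
               open  = fit_fraction_model(image, truth, ensemble_config(300, seed = 4), "open")$model,
               other = fit_fraction_model(image, truth, ensemble_config(300, seed = 5), "other")$model)
forest <- predict_fractions(models, image)$layers$forest
tex    <- texture_map(forest, glcm_config(metrics = "contrast"))$contrast
dem    <- simulate_dem(cfg, seed = 6)

mc <- movement_config(n_animals = 15, fix_interval_h = 1, step_sd = 110,
                      attraction_rate = 0.8, center_dispersion = 900,
                      center_drift = 300, window_sd = 0.3,
                      habitat_effect = list(sd_fc = 0.4, texture2 = -0.35,
                                            ranef_sd = 0.3),
                      seed = 8)
relocs <- simulate_relocations(mc, landscape = list(forest = forest,
                                                    texture = tex, dem = dem))
hr  <- estimate_home_ranges(relocs, windowing_config("monthly"), levels = 90)
cov <- build_covariate_table(hr, forest, tex, dem)
head(cov[, c("animal_id", "window", "area_km2", "mean_fc", "sd_fc", "texture")], 3)
#>   animal_id   window area_km2  mean_fc    sd_fc  texture
#> 1      A001 2006-M05   0.0558 63.26986 43.05110 33.13387
#> 2      A001 2006-M06   0.0945 40.37866 43.52712 24.46667
#> 3      A001 2006-M07   0.0657 47.15103 42.13234 39.10616

model <- habitat_model(cov, random_candidates = c("animal_id", "sex"))
summary(model)
#> Linear mixed habitat model of log home-range area
#>   n = 75  random intercepts: animal_id
#>   retained fixed effects: sd_fc, texture, texture2
#>   AIC 68.3, logLik -28.2
#>             estimate     se        t
#> (Intercept)  -2.2193 0.0971 -22.8602
#> sd_fc         0.4029 0.0908   4.4386
#> texture       0.0004 0.0754   0.0051
#> texture2     -0.3168 0.0506  -6.2598
#> ...
#> Explained deviance (%):
#>        term   type explained_deviance
#> 1     sd_fc  fixed              10.08
#> 2   texture  fixed              26.89
#> 3 animal_id random              16.01
```

The selection kept exactly the planted structure: the cover-variability
effect is recovered at 0.40 (planted 0.40), the concave texture effect at
−0.32 (planted −0.35, slightly attenuated by window-level measurement
error), the individual intercept is retained, and the null covariates
(mean cover, elevation, elevation²) were eliminated. The linear texture
term rides along because a linear term is protected while its quadratic
survives.

The whole chain also runs from one YAML config:

```r
res <- run_pipeline("config.yaml")   # simulate → fractions → texture →
make_report(res)                     # ranges → covariates → models + figures
```

or from a shell via `inst/scripts/rangecover.R run config.yaml out/`.

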