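---
title: "Continuous land cover and home-range size: models and methods"
author: "rangecover"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the pipeline

Categorical land-cover maps force every pixel into one class and therefore
hide within-class variation that animals plausibly respond to. This package
implements an analysis chain that replaces the categorical map by
*fractional cover* — per-pixel percentages of forest, open and other cover —
and asks how the resulting continuous description of the landscape explains
variation in home-range size of a large, range-resident herbivore such as
red deer:

1. **Fractional cover** (`aggregate_fractions()`, `fit_fraction_model()`,
   `predict_fractions()`): a fine categorical map is aggregated into exact
   per-class percentages on the coarser image grid; a random-forest
   regression (1000 trees by default, `mtry = floor(bands / 3)`) learns the
   map from pixel spectra to percent cover per class and predicts it
   wall-to-wall, with out-of-bag (OOB) accuracy as the honest error
   estimate. Predicted class layers are clipped to [0, 100] and rescaled
   per pixel to sum to 100, because independent per-class regressions do
   not close on their own; the pre-normalization sum is kept as a
   diagnostic layer.
2. **Home ranges** (`thin_relocations()`, `make_windows()`, `kernel_ud()`,
   `isopleth()`): GPS fixes are thinned to a one-hour minimum interval,
   restricted to a May–September season, split into monthly, biweekly or
   weekly windows (at least 10 fixes each), and each window's utilization
   distribution is estimated by the fixed bivariate-Gaussian kernel with
   the reference bandwidth
   $h = \tfrac12 (s_x + s_y)\, n^{-1/6}$.
   Home ranges are the 50 / 70 / 90 % isopleths: the smallest grid regions
   holding that share of the probability mass.
3. **Texture** (`texture_map()`, `size_dependency_screen()`): second-order
   Haralick statistics of the forest-fraction layer from the gray-level
   co-occurrence matrix (GLCM) of every pixel's 3×3 neighbourhood, pooled
   symmetrically over the four distance-1 directions. The headline metric
   is *contrast*, $\sum_{i,j}(i-j)^2 p_{ij}$, a measure of local
   variation; the buffer screen (500–7000 m rings around 90 %-isopleth
   centres) ranks metrics by how much their mean depends on buffer size
   (coefficient of variation of the radius profile).
4. **Covariates and model** (`build_covariate_table()`,
   `habitat_model()`): per home range, the mean and standard deviation of
   forest cover, mean contrast and mean elevation; areas are
   natural-log-transformed. A linear mixed model of log area is selected
   in two phases: random-intercept structure (candidates: individual, sex,
   year) by REML likelihood-ratio tests and AIC, then backward elimination
   of fixed effects under ML at an inclusive $|t| \ge 2$ threshold, with
   texture and elevation entering as centred quadratics and a linear term
   protected while its quadratic survives. The final model is refit by
   REML.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `aggregation_factor` | 6 | fine cells per coarse pixel per axis (5 m → 30 m) |
| `n_trees`, `predictors_per_split` | 1000, `floor(bands/3)` | ensemble size and split width |
| `min_interval_h` | 1 h | thinning interval for fixes |
| `min_locations` | 10 | minimum fixes per temporal window |
| `grid_res` | 30 m | UD grid; matches the imagery |
| UD margin | `5 h` | grid padding around the fixes |
| `n_levels` | 16 over [0, 100] | GLCM quantization, fixed scale so texture is comparable across ranges |
| `t_threshold` | 2 (inclusive) | fixed-effect retention |
| collinearity threshold | 0.7 | absolute Pearson r above which the later-priority variable is dropped |

Quantization uses the fixed [0, 100] percent scale rather than per-image
ranges so that one unit of contrast means the same thing inside every home
range. The reference bandwidth uses a single h for both axes, the
convention of the classic home-range software. Cells belong to a zone when
their centre falls inside it. Optional spatial-outlier removal is a speed
filter (`max_speed`, off by default) since no standard rule exists.

# What the synthetic data emulates

`simulate_fine_landcover()` thresholds a smoothed Gaussian random field at
the quantiles of the class proportions, so realized composition tracks the
target and patch size grows with `correlation_length`. Two optional
refinements make the landscape statistically more like a real montane
forest mosaic, and both are needed for the planted-effect experiments:

* a **compositional trend** (`trend_length`, `trend_weight`): a second,
  slowly varying field mixed into the latent surface, so local forest
  proportion drifts across kilometres (physiographic gradients);
* a **grain field** (`grain_lengths`, `grain_mix_length`): the patch
  component blends a fine- and a coarse-grained field with a smoothly
  varying weight, so the *arrangement* of the mosaic varies independently
  of its *composition*. Without this, windowed cover variability and GLCM
  contrast are nearly collinear (r ≈ 0.86 on a single-scale field) and the
  analysis could not separate them — real landscapes keep them below the
  0.7 screen, and so does this generator (r ≈ 0.45).

`simulate_coarse_image()` mixes per-class endmember spectra linearly by
the exact sub-pixel fractions and adds i.i.d. Gaussian sensor noise; with
zero noise the image is exactly linear in the fractions.
`simulate_dem()` rescales a smooth field to a 600–1450 m montane range.

`simulate_relocations()` produces range-resident tracks: a discrete-time
Ornstein–Uhlenbeck process whose stationary positional sd is
`step_sd / sqrt(2 * attraction_rate)`. Two deliberately realistic
features: each animal's activity centre drifts every calendar month
(`center_drift`), and the monthly range scale carries behavioural noise
(`window_sd`, a log-area sd, default 0.25) — real telemetry shows large
unexplained month-to-month variation in range size, and both features are
what makes a planted habitat effect identifiable at the window level
rather than only between animals. Fix schedules are regular
(`fix_interval_h`) with one near-duplicate fix per 200 as thinning fodder;
the real collars' burst schedules are not emulated.

## Planted habitat effects and what recovery can show

With `habitat_effect`, the monthly positional sd is scaled by
$\exp\{\tfrac12(\beta^\top z_{im} + b_i + \eta_{im})\}$, where $z_{im}$
are standardized local covariates measured in a disc of the expected 90 %
isopleth radius around the month's centre (the disc tracks the realized
extent through a short bounded fixed-point, including the known
kernel-oversmoothing factor $\sqrt{1 + n^{-1/3}}$), $b_i$ is the
individual intercept and $\eta_{im}$ the behavioural noise. Because the
90 % isopleth area is proportional to the squared positional sd, the
planted coefficients live directly on the log-area scale, and the full
pipeline (tracks → thinning → kernel ranges → zonal covariates → selected
mixed model) should return them.

Two genuine phenomena limit recovery fidelity, and are worth knowing about
when interpreting real analyses of this design:

* **size-elasticity of windowed variability**: the SD of fractional cover
  inside a window grows mechanically with window size (measured elasticity
  ≈ 0.17 per log radius on these landscapes), so any noise in realized
  range size leaks into the measured covariate with a positive sign;
* **errors-in-variables attenuation**: window-level covariates are
  measured with error, and a mixed model weights the noisy within-animal
  contrast heavily; the quadratic term is hit hardest (≈ 0.85
  multiplicative attenuation under the recovery conditions below).

Passing the recovery tests therefore shows the chain is unbiased up to
these measurement effects on a landscape with the assumed structure; it
does not certify the much messier measurement process of real collars and
imagery.

## Recovery-study conditions

The parameter-recovery experiments use one fixed landscape of 1800×1800
fine cells at 5 m (9×9 km; grain scales 25/150 m mixed at 1200 m, trend
2000 m at weight 0.45), an ensemble of 300 trees trained on 4000 sampled
pixels, and per replicate 40 animals over one May–September season at 1-h
fixes (attraction 0.8 h⁻¹, stationary sd ≈ 253 m, centre dispersion
2800 m, monthly drift 1000 m, behavioural noise 0.35), with effects
+0.4 (SD of cover), −0.35 (texture²) and an individual intercept sd of
0.3, analysed at the monthly × 90 % scale. These sizes keep a 25-replicate
experiment to a few minutes while leaving ≈ 200 model rows per replicate.

# Numerical choices and degenerate inputs

* Gaussian smoothing uses FFT-based circular convolution, so kernels wider
  than the field are handled and edge statistics stay stationary.
* `aggregate_fractions()` counts integer cells; the percent conversion is
  exact rational arithmetic realized in doubles, so class sums equal 100
  to 1e-9.
* A constant percent-cover response is a degenerate-response error, not a
  silently perfect fit; all-identical relocations are a
  degenerate-dispersion error; an all-nodata UD is an empty-UD error;
  windows below 10 fixes are dropped and logged, and partial trailing
  calendar blocks are kept but flagged.
* GLCM windows with fewer than 4 valid (non-nodata) pairs yield nodata;
  correlation of a zero-variance window is defined as 0.
* Mixed models use lme4; singular variance components are treated as
  removable during structure selection; ties in AIC go to the simpler
  structure, and the individual grouping is dropped last. Refitting the
  selected model on the same table reproduces coefficients exactly.
* Explained deviance is a drop-one ratio on ML deviances relative to the
  intercept-plus-random-effects model. The ratio is undefined when the
  null deviance is non-positive (response variance below ≈ 0.06 on the
  log scale); the function then returns no values and warns rather than
  reporting a meaningless number.
* Covariates are z-scored before fitting; coefficients are reported per
  SD and per original unit (quadratics per squared centred unit).

# Known limitations

* The isopleth region is a set of grid cells; its polygons are traced cell
  boundaries, so areas are grid-quantized (30 m default).
* The reference bandwidth oversmooths clumped or multimodal ranges; the
  90 % isopleth of a normal cloud runs ≈ 13 % large at n = 500, visible in
  the acceptance ratio (≈ 1.13).
* Backward elimination at $|t| \ge 2$ keeps a spurious term in roughly a
  quarter of pure-null datasets with six candidate terms (≈ 0.95⁶) — a
  property of the procedure itself, visible in the null-removal rate.
* One Landsat-like 5-band date is simulated; multi-date stacking is
  supported by the ensemble (`predictors_per_split` recomputed) but not
  exercised by the generator.
* No behavioural realism beyond a drifting-centre OU process: no
  migration, no winter enclosure, no fix-failure process, no GPS error
  (collar accuracy ~16 m is far below the 30 m grid).
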