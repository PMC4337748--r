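# Study conditions for the end-to-end parameter-recovery experiment: a fixed
# 9 x 9 km landscape with stand-scale patchiness (spatially varying grain)
# inside a broad compositional gradient, and 40 collared animals per
# replicate. Built once per test session and cached.
.recovery_cache <- new.env(parent = emptyenv())

recovery_landscape <- function() {
  if (!is.null(.recovery_cache$land)) return(.recovery_cache$land)
  lcfg <- landscape_config(extent = c(1800L, 1800L),
                           correlation_length = 100,
                           trend_length = 2000, trend_weight = 0.45,
                           grain_lengths = c(25, 150),
                           grain_mix_length = 1200, seed = 101)
  fine <- simulate_fine_landcover(lcfg)
  spec <- spectral_model(noise_sd = 0.01, seed = 102)
  coarse <- simulate_coarse_image(fine, lcfg, spec)
  truth <- aggregate_fractions(fine, lcfg$aggregation_factor)
  ec <- function(s) ensemble_config(n_trees = 300L,
                                    max_training_pixels = 4000L, seed = s)
  models <- list(
    forest = fit_fraction_model(coarse, truth, ec(103), "forest")$model,
    open   = fit_fraction_model(coarse, truth, ec(104), "open")$model,
    other  = fit_fraction_model(coarse, truth, ec(105), "other")$model)
  pred <- predict_fractions(models, coarse)
  tex <- texture_map(pred$layers[["forest"]],
                     glcm_config(metrics = "contrast"))[["contrast"]]
  dem <- simulate_dem(lcfg, seed = 106)
  .recovery_cache$land <- list(forest = pred$layers[["forest"]],
                               texture = tex, dem = dem, config = lcfg)
  .recovery_cache$land
}

planted_effect <- list(sd_fc = 0.4, texture2 = -0.35, ranef_sd = 0.3)

recovery_movement <- function(seed) {
  movement_config(n_animals = 40L, fix_interval_h = 1, step_sd = 320,
                  attraction_rate = 0.8, center_dispersion = 2800,
                  center_drift = 1000, window_sd = 0.35,
                  habitat_effect = planted_effect, seed = seed)
}

# one full pipeline replicate: tracks -> home ranges -> covariates -> model
recovery_replicate <- function(seed, land = recovery_landscape()) {
  rel <- simulate_relocations(recovery_movement(seed), landscape = land)
  hr <- estimate_home_ranges(rel, windowing_config("monthly"), levels = 90,
                             seed = seed + 1L)
  cv <- build_covariate_table(hr, land$forest, land$texture, land$dem)
  fit <- suppressWarnings(
    habitat_model(cv, random_candidates = c("animal_id", "sex")))
  co <- fit$coefficients
  pick <- function(tm) if (tm %in% rownames(co))
    c(est = co[tm, "estimate"], se = co[tm, "se"]) else c(est = NA, se = NA)
  list(sd_fc = pick("sd_fc"), texture2 = pick("texture2"),
       grouping = fit$grouping, fit = fit)
}

# covariate-table simulator for the selection-behaviour experiments
# (model-level: no spatial pipeline involved)
sim_selection_table <- function(n_animals, n_windows = 5, beta = list(),
                                id_sd = 0.3, resid_sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_animals * n_windows
  d <- data.frame(
    animal_id = rep(sprintf("A%02d", seq_len(n_animals)), each = n_windows),
    sex = rep(rep(c("F", "M"), length.out = n_animals), each = n_windows),
    year = rep(rep(2004:2006, length.out = n_animals), each = n_windows))
  d$mean_fc <- rnorm(n, 50, 10)
  d$sd_fc <- rnorm(n, 20, 5)
  d$texture <- rnorm(n, 10, 3)
  d$elevation <- rnorm(n, 900, 150)
  b <- rnorm(n_animals, 0, id_sd)[rep(seq_len(n_animals), each = n_windows)]
  lp <- 0.2 + b
  for (v in names(beta)) {
    base <- sub("2$", "", v)
    z <- as.numeric(scale(d[[base]]))
    lp <- lp + beta[[v]] * if (grepl("2$", v)) z^2 else z
  }
  d$log_area <- lp + rnorm(n, 0, resid_sd)
  d
}
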