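test_that("fine land cover honours class proportions and degenerate configs", {
  cfg <- landscape_config(extent = c(600L, 600L), correlation_length = 100,
                          seed = 11)
  r <- simulate_fine_landcover(cfg)
  prop <- as.numeric(table(factor(rg_band(r), levels = 1:3))) / (600 * 600)
  expect_true(all(abs(prop - c(0.55, 0.35, 0.10)) < 0.05))

  pure <- landscape_config(extent = c(60L, 60L),
                           class_proportions = c(forest = 1.0), seed = 1)
  rp <- simulate_fine_landcover(pure)
  expect_true(all(rg_band(rp) == 1))

  expect_error(landscape_config(extent = c(601L, 600L)), "divisible")
  expect_error(landscape_config(class_proportions = c(forest = 0.6,
                                                      open = 0.6)),
               "sum to 1")
})

test_that("fine land cover is seed-deterministic and patchier at longer correlation", {
  cfg <- landscape_config(extent = c(300L, 300L), correlation_length = 80,
                          seed = 7)
  r1 <- simulate_fine_landcover(cfg)
  r2 <- simulate_fine_landcover(cfg)
  expect_identical(r1$values, r2$values)

  lag1 <- function(corr_len) {
    c2 <- landscape_config(extent = c(300L, 300L),
                           correlation_length = corr_len, seed = 7)
    m <- rg_band(simulate_fine_landcover(c2)) == 1
    cor(as.vector(m[, -300]), as.vector(m[, -1]))
  }
  expect_gt(lag1(200), lag1(20))
  expect_gt(lag1(20), lag1(0))
})

test_that("coarse image is an exact linear mixture when noiseless", {
  cfg <- landscape_config(extent = c(60L, 60L), correlation_length = 60,
                          seed = 3)
  fine <- simulate_fine_landcover(cfg)
  spec <- spectral_model(noise_sd = 0, seed = 4)
  img <- simulate_coarse_image(fine, cfg, spec)
  fr <- aggregate_fractions(fine, cfg$aggregation_factor)
  for (b in 1:5) {
    manual <- Reduce(`+`, lapply(seq_along(fr$classes), function(k)
      rg_band(fr$layers[[k]]) / 100 * spec$endmembers[fr$classes[k], b]))
    expect_lt(max(abs(rg_band(img, b) - manual)), 1e-9)
  }
  # pure-forest block reproduces the forest endmember exactly
  purecfg <- landscape_config(extent = c(12L, 12L),
                              class_proportions = c(forest = 1), seed = 1)
  pimg <- simulate_coarse_image(simulate_fine_landcover(purecfg), purecfg,
                                spec)
  expect_equal(as.numeric(pimg$values[1, 1, ]),
               as.numeric(spec$endmembers["forest", ]), tolerance = 1e-12)
})

test_that("spectral noise matches its nominal standard deviation", {
  cfg <- landscape_config(extent = c(600L, 600L), correlation_length = 100,
                          seed = 5)
  fine <- simulate_fine_landcover(cfg)
  clean <- simulate_coarse_image(fine, cfg, spectral_model(noise_sd = 0))
  noisy <- simulate_coarse_image(fine, cfg,
                                 spectral_model(noise_sd = 0.05, seed = 6))
  for (b in c(1, 5)) {
    resid_sd <- sd(rg_band(noisy, b) - rg_band(clean, b))   # 1e4 pixels
    expect_lt(abs(resid_sd - 0.05) / 0.05, 0.1)
  }
})

test_that("DEM is rescaled exactly to its bounds and reproducible", {
  cfg <- landscape_config(extent = c(120L, 120L), seed = 2)
  dem <- simulate_dem(cfg, min_elev = 600, max_elev = 1450, seed = 9)
  expect_equal(min(rg_band(dem)), 600)
  expect_equal(max(rg_band(dem)), 1450)
  expect_identical(dem$values, simulate_dem(cfg, 600, 1450, seed = 9)$values)
  flat <- simulate_dem(cfg, 1000, 1000, seed = 9)
  expect_true(all(rg_band(flat) == 1000))
})

test_that("movement model attains its closed-form stationary dispersion", {
  mc <- movement_config(n_animals = 3, fix_interval_h = 1,
                        attraction_rate = 0.2, step_sd = 80,
                        center_dispersion = 0, center_drift = 0,
                        window_sd = 0, seed = 21)
  rel <- simulate_relocations(mc)
  centers <- attr(rel, "centers")
  devs <- unlist(lapply(1:3, function(i) {
    d <- rel[rel$animal_id == sprintf("A%03d", i), ]
    c(d$x - centers[i, 1], d$y - centers[i, 2])
  }))
  expect_gt(length(devs), 2e4)
  target <- stationary_sd(mc)               # step_sd / sqrt(2 * rate)
  expect_lt(abs(sd(devs) - target) / target, 0.05)
})

test_that("relocation schedules, duplicates and determinism behave as specified", {
  mc <- movement_config(n_animals = 2, fix_interval_h = 2, seed = 31,
                        center_dispersion = 100)
  rel <- simulate_relocations(mc)
  a1 <- rel[rel$animal_id == "A001", ]
  a2 <- rel[rel$animal_id == "A002", ]
  expect_false(isTRUE(all.equal(a1$x, a2$x)))     # distinct tracks
  # deliberate near-duplicate fixes 30 s after every 200th scheduled fix
  gaps <- diff(as.numeric(a1$timestamp))
  expect_true(any(gaps == 30))
  expect_identical(rel, simulate_relocations(mc))
  expect_error(movement_config(n_animals = 0), "at least 1")
  expect_error(movement_config(fix_interval_h = 0.25), ">= 1 hour")

  collapse <- movement_config(n_animals = 1, attraction_rate = 50,
                              step_sd = 10, center_dispersion = 0,
                              center_drift = 0, window_sd = 0, seed = 5)
  relc <- simulate_relocations(collapse)
  expect_lt(sd(relc$x), 2)                        # fixes collapse to centre
})

test_that("relocation CSV round trip preserves timestamps and attributes", {
  mc <- movement_config(n_animals = 1, fix_interval_h = 6, seed = 3)
  rel <- simulate_relocations(mc)
  f <- withr::local_tempfile(fileext = ".csv")
  write_relocations(rel, f)
  back <- read_relocations(f)
  expect_equal(back$timestamp, rel$timestamp)
  expect_equal(back$x, rel$x, tolerance = 1e-6)
})
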