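test_that("thinning applies the greedy one-hour rule, season filter and dedup", {
  # fixes every 15 min for 4 h -> 5 kept fixes at exactly 1 h spacing
  times <- utc("2006-06-01 08:00:00") + seq(0, 4 * 3600, by = 900)
  thin <- thin_relocations(make_relocs(times), windowing_config())
  expect_equal(nrow(thin), 5)
  expect_equal(diff(as.numeric(thin$timestamp)), rep(3600, 4))
  expect_equal(thin$timestamp[1], times[1])

  # all fixes in April fall outside the May-September season
  april <- utc("2006-04-10 00:00:00") + (0:20) * 3600
  expect_equal(nrow(thin_relocations(make_relocs(april),
                                     windowing_config())), 0)

  # exact-duplicate timestamps collapse to one fix
  dup <- make_relocs(utc("2006-06-01 08:00:00") + c(0, 0, 3600, 7200))
  expect_equal(nrow(thin_relocations(dup, windowing_config())), 3)

  # unparseable timestamps are reported with their row
  bad <- make_relocs(utc("2006-06-01 08:00:00") + c(0, 3600))
  bad$timestamp <- c("2006-06-01T08:00:00Z", "not-a-time")
  expect_error(thin_relocations(bad, windowing_config()), "row")
})

test_that("thinning is idempotent and enforces the minimum gap on jittered input", {
  set.seed(8)
  times <- utc("2006-07-01 00:00:00") +
    sort(sample(0:(86400 * 10), 500))
  raw <- make_relocs(times)
  cfg <- windowing_config()
  once <- thin_relocations(raw, cfg)
  expect_true(all(diff(as.numeric(once$timestamp)) >= 3600))
  twice <- thin_relocations(once, cfg)
  expect_identical(once$timestamp, twice$timestamp)
})

test_that("speed filter drops fixes implying implausible movement", {
  times <- utc("2006-06-01 08:00:00") + (0:3) * 3600
  raw <- make_relocs(times, x = c(0, 100, 9000, 200), y = rep(0, 4))
  cfg <- windowing_config(max_speed = 5000)
  thin <- thin_relocations(raw, cfg)
  expect_false(9000 %in% thin$x)
  expect_equal(nrow(thin), 3)
})

test_that("temporal windows partition the season as specified", {
  # hourly fixes across the whole season
  times <- seq(utc("2006-05-01 00:00:00"), utc("2006-09-30 23:00:00"),
               by = 3600)
  tab <- make_relocs(times)
  wk <- make_windows(tab, windowing_config("weekly"))
  ids <- vapply(wk, `[[`, "", "window")
  # 153-day season: 21 complete weekly blocks plus one partial (included)
  expect_equal(length(ids), 22)
  expect_true(wk[[which(ids == "2006-W22")]]$partial)
  expect_false(any(vapply(wk[ids != "2006-W22"], `[[`, TRUE, "partial")))
  # every fix lands in exactly one window
  expect_equal(sum(vapply(wk, function(w) nrow(w$data), 0L)), length(times))

  mo <- make_windows(tab, windowing_config("monthly"))
  expect_setequal(vapply(mo, `[[`, "", "window"),
                  sprintf("2006-M%02d", 5:9))
  bi <- make_windows(tab, windowing_config("biweekly"))
  expect_equal(length(bi), 11)   # 10 complete 14-day blocks + 1 partial

  # windows below the minimum-location rule are dropped and logged
  few <- make_relocs(utc("2006-06-01 08:00:00") + (0:8) * 3600)  # 9 fixes
  w <- make_windows(few, windowing_config("monthly"))
  expect_length(w, 0)
  expect_equal(attr(w, "dropped")$n, 9)
})

test_that("reference bandwidth matches its closed form", {
  # unit case: sd_x = sd_y = 1, n = 64 -> h = 64^(-1/6) * 1 = 0.5
  set.seed(1)
  x <- as.numeric(scale(rnorm(64))); y <- as.numeric(scale(rnorm(64)))
  expect_equal(reference_bandwidth(x, y), 0.5, tolerance = 1e-12)

  # direct formula oracle and scale equivariance
  set.seed(2)
  for (i in 1:5) {
    px <- rnorm(10, sd = runif(1, 1, 300)); py <- rnorm(10, sd = 50)
    h <- reference_bandwidth(px, py)
    expect_equal(h, 0.5 * (sd(px) + sd(py)) * 10^(-1 / 6),
                 tolerance = 1e-12)
    expect_equal(reference_bandwidth(px * 3.7, py * 3.7), h * 3.7,
                 tolerance = 1e-10)
  }
  expect_error(reference_bandwidth(rep(1, 10), rep(2, 10)), "degenerate")
  expect_error(reference_bandwidth(1:4, 1:4), "at least 5")
})

test_that("kernel UD integrates to one and matches the direct kernel sum", {
  set.seed(3)
  x <- rnorm(40, 500, 60); y <- rnorm(40, 500, 60)
  ud <- kernel_ud(x, y, grid_res = 20)
  cell_area <- ud$grid$res^2
  expect_equal(sum(rg_band(ud$grid)) * cell_area, 1, tolerance = 1e-6)

  # brute-force Gaussian sum at probe cells, up to the renormalization factor
  cc <- rg_centers(ud$grid)
  direct <- function(cx, cy)
    mean(dnorm(cx, x, ud$h) * dnorm(cy, y, ud$h))
  norm <- sum(vapply(seq_along(cc$y), function(r)
    sum(vapply(cc$x, function(cx) direct(cx, cc$y[r]), 0)), 0)) * cell_area
  for (probe in list(c(2, 3), c(10, 12), c(17, 5))) {
    got <- rg_band(ud$grid)[probe[1], probe[2]]
    want <- direct(cc$x[probe[2]], cc$y[probe[1]]) / norm
    expect_equal(got, want, tolerance = 1e-9)
  }

  # a single point (placed at a cell centre) yields a discretized Gaussian
  # peaked at its containing cell
  ud1 <- kernel_ud(rep(105, 5), rep(195, 5), h = 25, grid_res = 10)
  dmat <- rg_band(ud1$grid)
  peak <- which(dmat == max(dmat), arr.ind = TRUE)
  rc <- rg_cell_of(ud1$grid, 105, 195)
  expect_equal(as.integer(peak[1, ]), c(rc$row, rc$col))
})

test_that("isopleths take minimal prefixes and nest across levels", {
  # enumerable two-cell distribution: masses 0.6 / 0.4
  g <- raster_grid(matrix(c(0.6, 0.4), 1, 2), res = 1)
  ud <- structure(list(grid = g, h = 1, n_points = 10),
                  class = "utilization_distribution")
  expect_equal(isopleth(ud, 50)$area_km2 * 1e6, 1)
  expect_equal(isopleth(ud, 70)$area_km2 * 1e6, 2)

  # concentrated UD: one cell at every level
  g1 <- raster_grid(matrix(c(1, 0, 0, 0), 2, 2), res = 1)
  ud1 <- structure(list(grid = g1, h = 1, n_points = 5),
                   class = "utilization_distribution")
  for (lv in c(50, 70, 90))
    expect_equal(isopleth(ud1, lv)$area_km2 * 1e6, 1)

  # nesting on random UDs
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rexp(100), 10, 10)
    gr <- raster_grid(m / sum(m) / 900, res = 30)
    udr <- structure(list(grid = gr, h = 30, n_points = 50),
                     class = "utilization_distribution")
    a <- vapply(c(50, 70, 90), function(lv) isopleth(udr, lv)$area_km2, 0)
    expect_true(all(diff(a) >= 0))
  }

  empty <- structure(list(grid = raster_grid(matrix(NA_real_, 2, 2), res = 1),
                          h = 1, n_points = 0),
                     class = "utilization_distribution")
  expect_error(isopleth(empty, 50), "empty")
  expect_error(isopleth(ud1, 100))
})

test_that("end-to-end home-range estimation produces a coherent table", {
  mc <- movement_config(n_animals = 2, fix_interval_h = 3, step_sd = 60,
                        attraction_rate = 0.3, center_dispersion = 200,
                        center_drift = 50, window_sd = 0.1, seed = 41)
  rel <- simulate_relocations(mc)
  hr <- estimate_home_ranges(rel, windowing_config("monthly"),
                             grid_res = 20)
  expect_equal(sort(unique(hr$table$level)), c(50, 70, 90))
  expect_true(all(hr$table$n_points >= 10))
  expect_true(all(hr$table$area_km2 > 0))
  # per animal x window, areas nest across levels
  for (key in unique(paste(hr$table$animal_id, hr$table$window))) {
    sub <- hr$table[paste(hr$table$animal_id, hr$table$window) == key, ]
    sub <- sub[order(sub$level), ]
    expect_true(all(diff(sub$area_km2) >= 0))
  }
})
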