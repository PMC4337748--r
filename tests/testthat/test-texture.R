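test_that("quantization bins values over a fixed range", {
  const <- raster_grid(matrix(42, 3, 3), res = 30)
  expect_true(all(rg_band(quantize(const, 16)) ==
                    floor(42 / 100 * 16)))
  two <- raster_grid(matrix(c(0, 100, 0, 100, 0, 100, 0, 100, 0), 3, 3),
                     res = 30)
  q2 <- rg_band(quantize(two, 2))
  expect_setequal(unique(as.vector(q2)), c(0, 1))
  # hand-computed assignment: bin width 100/4 = 25
  vals <- matrix(c(0, 10, 24.9, 25, 60, 75, 99, 100, 50), 3, 3)
  q4 <- rg_band(quantize(raster_grid(vals, res = 30), 4))
  expect_equal(q4, matrix(c(0, 0, 0, 1, 2, 3, 3, 3, 2), 3, 3))
  withna <- raster_grid(matrix(c(NA, 1:8), 3, 3), res = 30)
  expect_true(is.na(rg_band(quantize(withna, 4))[1, 1]))
})

test_that("window GLCMs are normalized, symmetric and match enumeration", {
  cfg <- glcm_config(n_levels = 4)
  # constant patch: all mass on one diagonal entry
  p <- glcm_window(matrix(2, 3, 3), cfg)
  expect_equal(p[3, 3], 1)
  expect_equal(sum(p), 1)

  # vertical stripes 0,1,0 with horizontal offsets only: mass on (0,1),(1,0)
  stripes <- matrix(rep(c(0, 1, 0), each = 3), 3, 3)
  hcfg <- glcm_config(n_levels = 2)
  hcfg$offsets <- rbind(c(0, 1))
  ph <- glcm_window(stripes, hcfg)
  expect_equal(ph[1, 2], 0.5)
  expect_equal(ph[2, 1], 0.5)
  expect_equal(haralick_contrast(ph), 1)

  set.seed(4)
  for (i in 1:10) {
    patch <- matrix(sample(0:3, 9, replace = TRUE), 3, 3)
    got <- glcm_window(patch, cfg)
    expect_equal(sum(got), 1)
    expect_equal(got, t(got))                    # symmetric accumulation
    expect_equal(got, bf_glcm(patch, 4))
  }
})

test_that("Haralick metrics match brute-force double sums", {
  set.seed(5)
  metrics <- c("contrast", "homogeneity", "dissimilarity", "entropy",
               "angular_second_moment", "correlation")
  for (i in 1:10) {
    p <- matrix(rexp(64), 8, 8); p <- (p + t(p)); p <- p / sum(p)
    for (m in metrics)
      expect_equal(haralick_metric(p, m), bf_metric(p, m),
                   tolerance = 1e-12)
  }
  diagp <- diag(8) / 8
  expect_equal(haralick_contrast(diagp), 0)
  off <- matrix(0, 2, 2); off[1, 2] <- 0.5; off[2, 1] <- 0.5
  expect_equal(haralick_contrast(off), 1)
})

test_that("texture maps equal per-pixel brute force and hit known bounds", {
  cfg <- glcm_config(n_levels = 4)
  set.seed(6)
  vals <- matrix(runif(100, 0, 100), 10, 10)
  r <- raster_grid(vals, res = 30)
  maps <- texture_map(r, cfg)
  lv <- rg_band(quantize(r, 4))
  for (m in names(maps))
    expect_equal(rg_band(maps[[m]]), bf_texture_map(lv, 4, m))
  # edges are nodata
  expect_true(all(is.na(rg_band(maps$contrast)[1, ])))
  expect_true(all(is.na(rg_band(maps$contrast)[, 10])))

  # constant raster: zero contrast everywhere interior
  cm <- texture_map(raster_grid(matrix(55, 8, 8), res = 30), cfg)
  expect_true(all(rg_band(cm$contrast)[2:7, 2:7] == 0))

  # two-level checkerboard attains the (n_levels - 1)^2 bound... at the
  # diagonal-free horizontal/vertical pairs; with diagonals included the
  # interior value is the pair-weighted mixture, <= the bound
  chk <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 0, 100))
  hv <- glcm_config(n_levels = 16)
  hv$offsets <- rbind(c(0, 1), c(1, 0))
  cb <- texture_map(raster_grid(chk, res = 30), hv)
  expect_true(all(rg_band(cb$contrast)[2:7, 2:7] == 15^2))
  full <- texture_map(raster_grid(chk, res = 30), glcm_config(n_levels = 16))
  expect_true(all(rg_band(full$contrast)[2:7, 2:7] <= 15^2))
})

test_that("texture maps rotate with their input under the symmetric offset set", {
  set.seed(7)
  vals <- matrix(runif(81, 0, 100), 9, 9)
  cfg <- glcm_config(n_levels = 8)
  rot90 <- function(m) t(m)[, nrow(m):1]
  m1 <- rg_band(texture_map(raster_grid(vals, res = 30), cfg)$contrast)
  m2 <- rg_band(texture_map(raster_grid(rot90(vals), res = 30),
                            cfg)$contrast)
  expect_equal(m2, rot90(m1))
})

test_that("nodata windows fall back to nodata below the valid-pair minimum", {
  vals <- matrix(runif(25, 0, 100), 5, 5)
  vals[2:4, 2] <- NA; vals[2:4, 4] <- NA; vals[2, 3] <- NA; vals[4, 3] <- NA
  maps <- texture_map(raster_grid(vals, res = 30), glcm_config(n_levels = 4))
  expect_true(is.na(rg_band(maps$contrast)[3, 3]))
})

test_that("range means and the size-dependency screen behave as specified", {
  tex <- raster_grid(matrix(7, 20, 20), res = 30)
  mask <- matrix(FALSE, 20, 20); mask[5:8, 5:8] <- TRUE
  hr <- structure(list(mask = raster_grid(mask * 1, res = 30),
                       animal_id = "A", window = "w"),
                  class = "home_range")
  mt <- mean_texture_in_range(tex, hr)
  expect_equal(mt$mean, 7)
  expect_equal(mt$n_cells, 16)

  # two known cells
  tex2 <- raster_grid(matrix(seq(0, 100, length.out = 16), 4, 4), res = 30)
  m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE; m2[2, 1] <- TRUE
  hr2 <- structure(list(mask = raster_grid(m2 * 1, res = 30)),
                   class = "home_range")
  v <- rg_band(tex2)
  expect_equal(mean_texture_in_range(tex2, hr2)$mean, mean(v[1:2, 1]))

  # constant texture: zero size-dependency score; permutation invariance
  centers <- cbind(c(300, 400), c(300, 250))
  sc <- size_dependency_screen(list(contrast = tex), centers,
                               radii = c(60, 120, 180))
  expect_equal(sc$scores$score, 0)
  set.seed(8)
  rnd <- raster_grid(matrix(runif(400), 20, 20) * 20, res = 30)
  s1 <- size_dependency_screen(list(contrast = rnd), centers,
                               radii = c(60, 120, 180))
  s2 <- size_dependency_screen(list(contrast = rnd), centers[2:1, ],
                               radii = c(60, 120, 180))
  expect_equal(s1$scores$score, s2$scores$score)

  # a strongly trending field is more size-dependent than a stationary one:
  # buffer means over a steep surface shift as the radius grows, while means
  # over a stationary field stay near the global mean
  trend <- raster_grid(outer(1:20, 1:20, function(i, j) (i / 2)^2),
                       res = 30)
  ctr2 <- cbind(c(90, 150), c(510, 450))   # near the flat corner
  st <- size_dependency_screen(list(contrast = rnd), ctr2,
                               radii = c(60, 120, 180))$scores$score
  tr <- size_dependency_screen(list(contrast = trend), ctr2,
                               radii = c(60, 120, 180))$scores$score
  expect_gt(tr, st)
})
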