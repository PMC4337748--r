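#' Configuration for a synthetic landscape
#'
#' Describes the paired fine/coarse landscape the generator produces: a fine
#' categorical land-cover map over the classes forest / open / other, which
#' nests exactly into a coarser multiband image grid (`aggregation_factor`
#' fine cells per coarse cell per axis).
#'
#' @param fine_resolution fine cell size in metres (default 5, the scale of an
#'   aerial-photo classification).
#' @param aggregation_factor integer >= 2, fine cells per coarse cell per axis
#'   (default 6, giving 30 m coarse pixels from 5 m fine cells).
#' @param extent integer vector `c(rows, cols)` of fine-cell counts; must be
#'   divisible by `aggregation_factor`.
#' @param class_proportions named fractions over forest/open/other, summing
#'   to 1. Defaults reflect a forest-dominated montane landscape.
#' @param correlation_length patch-size control in metres: the standard
#'   deviation of the Gaussian smoother applied to the white-noise field
#'   before quantile thresholding.
#' @param trend_length optional second, larger spatial scale in metres. Real
#'   landscapes are structured at several scales (stand-scale patchiness
#'   within physiographic gradients); when set, the thresholded field is a
#'   weighted mix of a patch-scale and a gradient-scale component, so local
#'   class composition drifts across the map.
#' @param trend_weight weight in [0, 1) of the gradient-scale component
#'   (default 0.5 when `trend_length` is set).
#' @param grain_lengths optional pair of patch scales in metres (e.g.
#'   `c(60, 240)`). When set, the patch component blends a fine-grained and
#'   a coarse-grained field with a weight that itself varies smoothly across
#'   the map, so the *grain* of the mosaic varies independently of its
#'   *composition*. This emulates a key property of real landscapes: texture
#'   (arrangement) and cover variability (composition) are related but not
#'   collinear.
#' @param grain_mix_length spatial scale (m) of the grain-weight field
#'   (default 1500).
#' @param seed integer RNG seed.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(fine_resolution = 5, aggregation_factor = 6L,
                             extent = c(600L, 600L),
                             class_proportions = c(forest = 0.55, open = 0.35,
                                                   other = 0.10),
                             correlation_length = 300, trend_length = NULL,
                             trend_weight = 0.5, grain_lengths = NULL,
                             grain_mix_length = 1500, seed = 1L) {
  stopifnot(fine_resolution > 0, aggregation_factor >= 2,
            length(extent) == 2, all(extent >= 1),
            correlation_length >= 0, !is.null(names(class_proportions)))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(extent %% aggregation_factor != 0))
    stop("extent (", paste(extent, collapse = "x"),
         ") not divisible by aggregation_factor (", aggregation_factor, ")")
  stopifnot(trend_weight >= 0, trend_weight < 1)
  structure(list(fine_resolution = fine_resolution,
                 aggregation_factor = as.integer(aggregation_factor),
                 extent = as.integer(extent),
                 class_proportions = class_proportions,
                 correlation_length = correlation_length,
                 trend_length = trend_length, trend_weight = trend_weight,
                 grain_lengths = grain_lengths,
                 grain_mix_length = grain_mix_length,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Separable Gaussian smoothing with circular (wrap-around) edges via the
# FFT; sigma in cells. Wrap-around keeps the field stationary so class
# proportions are respected near the edges, and the transform handles
# kernels wider than the field.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  wrap_kernel <- function(n) {
    d <- c(0:(n %/% 2), if (n > 2) -((n - n %/% 2 - 1):1))
    k <- stats::dnorm(d, sd = sigma)
    k / sum(k)
  }
  K <- outer(stats::fft(wrap_kernel(nrow(m))),
             stats::fft(wrap_kernel(ncol(m))))
  Re(stats::fft(stats::fft(m) * K, inverse = TRUE)) / length(m)
}

#' Simulate a fine-resolution categorical land-cover map
#'
#' Thresholds a smoothed Gaussian random field at the quantiles of the
#' configured class proportions, so realized class fractions track the
#' configuration and patch size grows with `correlation_length`.
#'
#' @param cfg a [landscape_config()].
#' @return categorical `raster_grid` with integer codes into
#'   `names(cfg$class_proportions)`.
#' @export
simulate_fine_landcover <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  set.seed(cfg$seed)
  nr <- cfg$extent[1]; nc <- cfg$extent[2]
  unitize <- function(m) if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m)
                         else m
  if (!is.null(cfg$grain_lengths)) {
    # patch component with spatially varying grain: blend a fine- and a
    # coarse-grained field; the blend weight drifts at grain_mix_length
    p1 <- unitize(gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                                  cfg$grain_lengths[1] / cfg$fine_resolution))
    p2 <- unitize(gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                                  cfg$grain_lengths[2] / cfg$fine_resolution))
    a <- stats::pnorm(unitize(gaussian_smooth(
      matrix(stats::rnorm(nr * nc), nr, nc),
      cfg$grain_mix_length / cfg$fine_resolution)))
    a <- 0.05 + 0.9 * a
    z <- a * p1 + sqrt(1 - a^2) * p2
  } else {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    z <- gaussian_smooth(z, cfg$correlation_length / cfg$fine_resolution)
  }
  if (!is.null(cfg$trend_length) && cfg$trend_weight > 0) {
    tr <- matrix(stats::rnorm(nr * nc), nr, nc)
    tr <- gaussian_smooth(tr, cfg$trend_length / cfg$fine_resolution)
    z <- sqrt(1 - cfg$trend_weight^2) * unitize(z) +
      cfg$trend_weight * unitize(tr)
  }
  p <- cfg$class_proportions
  cum <- cumsum(p)
  # quantile thresholding on the realized field: class k occupies the cells
  # between the cum[k-1] and cum[k] empirical quantiles
  qs <- stats::quantile(z, cum[-length(cum)], names = FALSE, type = 1)
  codes <- matrix(1L, nr, nc)
  for (k in seq_along(qs)) codes[z > qs[k]] <- k + 1L
  # classes with zero proportion produce duplicate thresholds; the findInterval
  # equivalent above already assigns them zero cells
  raster_grid(codes, res = cfg$fine_resolution, levels = names(p))
}

#' Spectral mixing model for the coarse image
#'
#' Per-class endmember reflectances for a 5-band sensor plus i.i.d. Gaussian
#' sensor noise. Default endmembers are plausible surface reflectances
#' (0-1 scale) for closed forest, open grassland and bright non-vegetated
#' cover in the blue/green/red/NIR/SWIR bands.
#'
#' @param endmembers class x band matrix of mean reflectances; rows named by
#'   class and pairwise distinct.
#' @param noise_sd per-band Gaussian noise standard deviation (recycled).
#' @param seed integer RNG seed.
#' @return object of class `spectral_model`.
#' @export
spectral_model <- function(endmembers = NULL, noise_sd = 0.01, seed = 1L) {
  if (is.null(endmembers)) {
    endmembers <- rbind(forest = c(0.03, 0.05, 0.03, 0.30, 0.12),
                        open   = c(0.06, 0.09, 0.08, 0.42, 0.25),
                        other  = c(0.10, 0.12, 0.14, 0.20, 0.18))
  }
  stopifnot(is.matrix(endmembers), !is.null(rownames(endmembers)),
            all(noise_sd >= 0))
  d <- as.matrix(stats::dist(endmembers))
  if (any(d[upper.tri(d)] == 0)) stop("endmember rows must be distinct")
  structure(list(endmembers = endmembers,
                 noise_sd = rep(noise_sd, length.out = ncol(endmembers)),
                 seed = as.integer(seed)),
            class = "spectral_model")
}

#' Simulate a coarse multiband image by linear mixing
#'
#' Each coarse pixel's band vector is the fraction-weighted mixture of the
#' class endmembers (fractions from exact sub-pixel aggregation of the fine
#' map) plus independent Gaussian noise.
#'
#' @param fine categorical `raster_grid` from [simulate_fine_landcover()].
#' @param cfg the matching [landscape_config()].
#' @param spec a [spectral_model()].
#' @return multiband `raster_grid` on the coarse grid.
#' @export
simulate_coarse_image <- function(fine, cfg, spec) {
  stopifnot(is_raster_grid(fine), inherits(spec, "spectral_model"))
  if (any(c(rg_nrow(fine), rg_ncol(fine)) %% cfg$aggregation_factor != 0))
    stop("fine grid does not nest into the coarse grid at factor ",
         cfg$aggregation_factor)
  fr <- aggregate_fractions(fine, cfg$aggregation_factor)
  classes <- fr$classes
  em <- spec$endmembers[classes, , drop = FALSE]
  nb <- ncol(em)
  nr <- rg_nrow(fr$layers[[1]]); nc <- rg_ncol(fr$layers[[1]])
  set.seed(spec$seed)
  arr <- array(0, dim = c(nr, nc, nb))
  for (b in seq_len(nb)) {
    bandmat <- matrix(0, nr, nc)
    for (k in seq_along(classes))
      bandmat <- bandmat + rg_band(fr$layers[[k]]) / 100 * em[k, b]
    if (spec$noise_sd[b] > 0)
      bandmat <- bandmat + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd[b]),
                                  nr, nc)
    arr[, , b] <- bandmat
  }
  raster_grid(arr, res = fine$res * cfg$aggregation_factor, xmin = fine$xmin,
              ymax = fine$ymax, crs = fine$crs)
}

#' Simulate a smooth digital elevation model
#'
#' A heavily smoothed Gaussian random field linearly rescaled so its minimum
#' and maximum equal the requested bounds (the default range matches a
#' montane study landscape).
#'
#' @param cfg a [landscape_config()]; the DEM is produced on the coarse grid.
#' @param min_elev,max_elev elevation bounds in metres.
#' @param seed integer RNG seed.
#' @param relief_length smoothing length (m) of the terrain; defaults to five
#'   times the land-cover correlation length so relief varies more slowly
#'   than vegetation.
#' @return single-band `raster_grid` of elevations.
#' @export
simulate_dem <- function(cfg, min_elev = 600, max_elev = 1450, seed = 1L,
                         relief_length = NULL) {
  stopifnot(min_elev <= max_elev)
  coarse_res <- cfg$fine_resolution * cfg$aggregation_factor
  nr <- cfg$extent[1] / cfg$aggregation_factor
  nc <- cfg$extent[2] / cfg$aggregation_factor
  if (is.null(relief_length)) relief_length <- 5 * cfg$correlation_length
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- gaussian_smooth(z, relief_length / coarse_res)
  rng <- range(z)
  z <- if (rng[1] == rng[2] || min_elev == max_elev)
    matrix((min_elev + max_elev) / 2, nr, nc)
  else min_elev + (z - rng[1]) / (rng[2] - rng[1]) * (max_elev - min_elev)
  raster_grid(z, res = coarse_res)
}

#' Configuration for telemetry simulation
#'
#' Describes a set of range-resident animals tracked over one summer season.
#' Tracks follow a discrete-time mean-reverting (Ornstein-Uhlenbeck)
#' process around a per-animal centre; the stationary positional standard
#' deviation `step_sd / sqrt(2 * attraction_rate)` controls true range size.
#' An optional `habitat_effect` plants a known log-linear dependence of each
#' animal's range scale on the landscape at its centre, for parameter
#' recovery (see [simulate_relocations()]).
#'
#' @param n_animals number of animals (>= 1).
#' @param sex_ratio fraction of females; sexes are assigned round-robin.
#' @param season character or Date vector `c(start, end)`; default one
#'   May 1 - Sep 30 season.
#' @param fix_interval_h hours between scheduled fixes (>= 1).
#' @param center_dispersion standard deviation (m) of the Gaussian scatter of
#'   range centres around the landscape midpoint.
#' @param center_drift standard deviation (m) of the monthly shift of each
#'   animal's activity centre around its seasonal centre (default 400).
#'   Range-resident ungulates shift their centre of activity within the
#'   season; this also gives each animal genuine month-to-month habitat
#'   variation, which is what makes a planted habitat effect identifiable
#'   from both the between- and within-animal contrasts.
#' @param attraction_rate mean-reversion rate per hour (> 0).
#' @param step_sd diffusive step scale in m / sqrt(h); stationary positional
#'   sd is `step_sd / sqrt(2 * attraction_rate)`.
#' @param habitat_effect optional named list of planted coefficients on the
#'   log home-range-area scale over standardized local covariates:
#'   any of `mean_fc`, `sd_fc`, `texture`, `texture2`, `elevation`,
#'   `elevation2`, plus `ranef_sd` (per-animal random-intercept sd).
#' @param window_sd month-to-month behavioural variation of an animal's
#'   range scale, as a standard deviation on the log-area scale (default
#'   0.25): each calendar month the animal's positional sd is scaled by
#'   `exp(0.5 * eta)`, `eta ~ N(0, window_sd^2)`. Real telemetry shows
#'   substantial unexplained window-to-window variation in range size;
#'   without it the simulated monthly areas would be implausibly stable.
#' @param seed integer RNG seed.
#' @return object of class `movement_config`.
#' @export
movement_config <- function(n_animals = 10L, sex_ratio = 0.5,
                            season = c("2006-05-01", "2006-09-30"),
                            fix_interval_h = 1, center_dispersion = 1000,
                            center_drift = 400,
                            attraction_rate = 0.15, step_sd = 140,
                            habitat_effect = NULL, window_sd = 0.25,
                            seed = 1L) {
  if (n_animals < 1) stop("n_animals must be at least 1")
  if (fix_interval_h < 1) stop("fix_interval_h must be >= 1 hour")
  if (attraction_rate <= 0) stop("attraction_rate must be positive")
  season <- as.Date(season)
  stopifnot(length(season) == 2, season[1] < season[2])
  structure(list(n_animals = as.integer(n_animals), sex_ratio = sex_ratio,
                 season = season, fix_interval_h = fix_interval_h,
                 center_dispersion = center_dispersion,
                 center_drift = center_drift,
                 attraction_rate = attraction_rate, step_sd = step_sd,
                 habitat_effect = habitat_effect, window_sd = window_sd,
                 seed = as.integer(seed)),
            class = "movement_config")
}

#' Stationary positional standard deviation of the movement model
#' @param cfg a [movement_config()].
#' @return stationary sd in metres (per axis).
#' @export
stationary_sd <- function(cfg) cfg$step_sd / sqrt(2 * cfg$attraction_rate)

# local covariates in a disc around (x0, y0): mean/sd of forest fraction,
# mean texture, mean elevation, from whichever layers are supplied
disc_covariates <- function(x0, y0, radius, layers) {
  out <- c(mean_fc = NA_real_, sd_fc = NA_real_, texture = NA_real_,
           elevation = NA_real_)
  grab <- function(r) {
    cc <- rg_centers(r)
    ci <- which(abs(cc$x - x0) <= radius)
    ri <- which(abs(cc$y - y0) <= radius)
    if (length(ci) == 0 || length(ri) == 0) return(numeric(0))
    d2 <- outer((cc$y[ri] - y0)^2, (cc$x[ci] - x0)^2, "+")
    v <- rg_band(r)[ri, ci, drop = FALSE][d2 <= radius^2]
    v[!is.na(v)]
  }
  if (!is.null(layers$forest)) {
    v <- grab(layers$forest)
    if (length(v) > 1) { out["mean_fc"] <- mean(v); out["sd_fc"] <- stats::sd(v) }
  }
  if (!is.null(layers$texture)) {
    v <- grab(layers$texture); if (length(v) > 0) out["texture"] <- mean(v)
  }
  if (!is.null(layers$dem)) {
    v <- grab(layers$dem); if (length(v) > 0) out["elevation"] <- mean(v)
  }
  out
}

#' Simulate GPS relocations for range-resident animals
#'
#' Generates per-animal tracks from a discrete-time Ornstein-Uhlenbeck
#' process around Gaussian-scattered centres, with fixes on a regular
#' schedule over the season plus one deliberate near-duplicate fix per 200
#' fixes (so the one-hour thinning filter has something to remove). Sex and
#' year are assigned round-robin.
#'
#' Each animal's activity centre shifts every calendar month (Gaussian
#' drift of sd `center_drift` around the seasonal centre), so successive
#' monthly ranges sample genuinely different habitat.
#'
#' With a `habitat_effect` in `cfg` and a `landscape` bundle, the monthly
#' positional sd is scaled by `exp(0.5 * (beta . z_im + b_i + eta_im))`:
#' `z_im` are the standardized local covariates in a disc of the expected
#' 90% isopleth radius around animal i's month-m centre, `b_i` is a
#' per-animal normal random intercept and `eta_im` the behavioural month
#' noise. Because the 90% isopleth area is proportional to the squared
#' positional sd, the planted coefficients live directly on the log-area
#' scale; they are recorded in `attr(result, "planted")` together with the
#' standardization constants and the per-month linear predictors.
#'
#' @param cfg a [movement_config()].
#' @param landscape optional named list with `raster_grid` entries `forest`
#'   (percent forest cover), `texture` and `dem`, used only when
#'   `cfg$habitat_effect` is set. A [fraction_stack] may be passed instead,
#'   in which case its forest layer is used.
#' @return data.frame (`animal_id`, `sex`, `year`, `timestamp`, `x`, `y`)
#'   sorted by animal then time, with planted-effect metadata attached when
#'   applicable.
#' @export
simulate_relocations <- function(cfg, landscape = NULL) {
  stopifnot(inherits(cfg, "movement_config"))
  set.seed(cfg$seed)
  if (inherits(landscape, "fraction_stack"))
    landscape <- list(forest = landscape$layers[["forest"]])
  eff <- cfg$habitat_effect
  sigma0 <- stationary_sd(cfg)

  # landscape midpoint for centre scatter (fall back to origin-free default)
  ref <- landscape$forest %||% landscape$texture %||% landscape$dem
  if (!is.null(ref)) {
    cx <- ref$xmin + rg_ncol(ref) * ref$res / 2
    cy <- ref$ymax - rg_nrow(ref) * ref$res / 2
    half <- c(rg_ncol(ref), rg_nrow(ref)) * ref$res / 2
  } else {
    cx <- 0; cy <- 0; half <- c(Inf, Inf)
  }
  margin <- min(3 * sigma0, half[1] / 2)
  draw_center <- function() {
    # rejection sampling keeps the Gaussian scatter but avoids piling
    # centres up on the interior boundary
    for (try in 1:200) {
      p <- stats::rnorm(2, c(cx, cy), cfg$center_dispersion)
      if (abs(p[1] - cx) <= half[1] - margin &&
          abs(p[2] - cy) <= half[2] - margin) return(p)
    }
    c(cx, cy)
  }
  centers <- t(vapply(seq_len(cfg$n_animals), function(i) draw_center(),
                      numeric(2)))

  dt <- cfg$fix_interval_h
  t0 <- as.POSIXct(paste(cfg$season[1], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(cfg$season[2], "23:59:59"), tz = "UTC")
  times <- seq(t0, t1, by = dt * 3600)
  n <- length(times)
  phi <- exp(-cfg$attraction_rate * dt)
  sexes <- rep(c("F", "M"), length.out = cfg$n_animals)
  if (cfg$sex_ratio == 1) sexes[] <- "F"
  if (cfg$sex_ratio == 0) sexes[] <- "M"
  year <- as.integer(format(cfg$season[1], "%Y"))
  months <- as.integer(format(times, "%m"))
  month_levels <- unique(months)
  nm <- length(month_levels)
  na <- cfg$n_animals

  # monthly activity centres: seasonal centre + Gaussian drift, kept inside
  # the landscape margin
  cim_x <- matrix(stats::rnorm(na * nm, 0, cfg$center_drift), na, nm) +
    centers[, 1]
  cim_y <- matrix(stats::rnorm(na * nm, 0, cfg$center_drift), na, nm) +
    centers[, 2]
  cim_x <- pmin(pmax(cim_x, cx - half[1] + margin), cx + half[1] - margin)
  cim_y <- pmin(pmax(cim_y, cy - half[2] + margin), cy + half[2] - margin)

  b <- stats::rnorm(na, 0, if (!is.null(eff)) eff$ranef_sd %||% 0 else 0)
  eta <- matrix(stats::rnorm(na * nm, 0, cfg$window_sd), na, nm)

  planted <- NULL
  lp_im <- matrix(0, na, nm)              # planted log-area offset per month
  if (!is.null(eff)) {
    if (is.null(ref)) stop("habitat_effect requires a landscape")
    r90 <- sigma0 * sqrt(2 * log(10))     # 90% radius of a circular normal
    # planted coefficients act per SD of the covariate distribution across
    # all animal-months (matching how the habitat model standardizes)
    lp_of <- function(zrow) {             # zrow: named numeric vector
      nms <- intersect(names(eff), names(zrow))
      lp <- sum(unlist(eff[nms]) * zrow[nms])
      for (v in names(zrow))               # quadratic terms, e.g. texture2
        if (!is.null(eff[[paste0(v, "2")]]))
          lp <- lp + eff[[paste0(v, "2")]] * zrow[[v]]^2
      lp
    }
    measure_z <- function(radii) {
      cvmat <- t(vapply(seq_len(na * nm), function(k)
        disc_covariates(cim_x[k], cim_y[k], radii[k], landscape),
        numeric(4)))
      ctr <- colMeans(cvmat, na.rm = TRUE)
      scl <- apply(cvmat, 2, stats::sd, na.rm = TRUE)
      z <- sweep(sweep(cvmat, 2, ctr), 2, ifelse(scl > 0, scl, 1), "/")
      z[!is.finite(z)] <- 0
      list(z = z, center = ctr, scale = scl)
    }
    # the reference-bandwidth kernel oversmooths a normal range by a known
    # factor, so the region an animal's range occupies (and the pipeline
    # measures) is wider than the raw positional spread
    n_month <- max(table(months))
    halo <- sqrt(1 + n_month^(-1 / 3))
    st <- measure_z(rep(r90 * halo, na * nm))
    lp0 <- matrix(apply(st$z, 1, lp_of), na, nm) + b + eta
    # bounded fixed-point updates so the planted disc tracks the month's
    # realized range extent (the covariates an animal responds to are those
    # of the range it actually uses)
    for (it in 1:2) {
      rfac <- pmin(pmax(exp(0.25 * as.vector(lp0)), 0.5), 2)
      st <- measure_z(r90 * halo * rfac)
      lp0 <- matrix(apply(st$z, 1, lp_of), na, nm) + b + eta
    }
    zmat <- st$z
    ctr <- st$center; scl <- st$scale
    lp_im <- matrix(apply(zmat, 1, lp_of), na, nm) + b
    planted <- list(coefficients = eff[setdiff(names(eff), "ranef_sd")],
                    ranef_sd = eff$ranef_sd %||% 0,
                    scalers = list(center = ctr, scale = scl),
                    z = zmat, ranef = b, months = month_levels,
                    log_area_offset = lp_im)
  }
  lp_im <- lp_im + eta                    # behavioural month noise

  out <- vector("list", na)
  mi <- match(months, month_levels)
  for (i in seq_len(na)) {
    sig_m <- sigma0 * exp(0.5 * lp_im[i, ])
    x <- numeric(n); y <- numeric(n)
    devx <- stats::rnorm(1, sd = sig_m[1])
    devy <- stats::rnorm(1, sd = sig_m[1])
    for (m in seq_len(nm)) {
      idx <- which(mi == m)
      innov <- sig_m[m] * sqrt(1 - phi^2)
      segx <- as.numeric(stats::filter(stats::rnorm(length(idx), sd = innov),
                                       phi, method = "recursive",
                                       init = devx))
      segy <- as.numeric(stats::filter(stats::rnorm(length(idx), sd = innov),
                                       phi, method = "recursive",
                                       init = devy))
      x[idx] <- segx + cim_x[i, m]
      y[idx] <- segy + cim_y[i, m]
      devx <- segx[length(segx)]; devy <- segy[length(segy)]
    }
    ts <- times
    # near-duplicate fixes every 200 scheduled fixes, 30 s after the original
    dupidx <- seq(200L, n, by = 200L)
    if (length(dupidx) > 0) {
      ts <- c(ts, times[dupidx] + 30)
      x <- c(x, x[dupidx] + stats::rnorm(length(dupidx), sd = 5))
      y <- c(y, y[dupidx] + stats::rnorm(length(dupidx), sd = 5))
    }
    o <- order(ts)
    out[[i]] <- data.frame(animal_id = sprintf("A%03d", i), sex = sexes[i],
                           year = year, timestamp = ts[o], x = x[o], y = y[o])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "planted") <- planted
  attr(res, "centers") <- centers
  attr(res, "monthly_centers") <- list(x = cim_x, y = cim_y)
  attr(res, "stationary_sd") <- sigma0 * exp(0.5 * lp_im)
  res
}

#' Write / read a relocation table as CSV
#'
#' Columns `animal_id,sex,year,timestamp,x,y` with ISO-8601 UTC timestamps.
#' @param relocs relocation data.frame.
#' @param path CSV path.
#' @return invisibly `path` (write) / the data.frame (read).
#' @export
write_relocations <- function(relocs, path) {
  out <- relocs
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_relocations
#' @export
read_relocations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  df
}
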