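#' Windowing and filtering configuration for home-range estimation
#'
#' @param scheme temporal scale: `"monthly"` (calendar months), `"biweekly"`
#'   (consecutive 14-day blocks anchored at `season_start`) or `"weekly"`
#'   (7-day blocks).
#' @param season_start,season_end season bounds (dates, year ignored when
#'   applied: the month-day is used per year present in the data). Defaults
#'   May 1 / Sep 30.
#' @param min_locations minimum fixes for a window to be estimated
#'   (default 10).
#' @param min_interval_h minimum interval between retained fixes in hours
#'   (default 1).
#' @param max_speed optional speed filter in m/h: fixes implying a faster
#'   move than this from the previously kept fix are dropped as spatial
#'   outliers. Off (`NULL`) by default since no standard rule exists.
#' @return object of class `windowing_config`.
#' @export
windowing_config <- function(scheme = c("monthly", "biweekly", "weekly"),
                             season_start = "05-01", season_end = "09-30",
                             min_locations = 10L, min_interval_h = 1,
                             max_speed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(min_locations >= 1, min_interval_h > 0)
  structure(list(scheme = scheme, season_start = season_start,
                 season_end = season_end,
                 min_locations = as.integer(min_locations),
                 min_interval_h = min_interval_h, max_speed = max_speed),
            class = "windowing_config")
}

season_bounds <- function(cfg, year) {
  list(start = as.POSIXct(paste0(year, "-", cfg$season_start, " 00:00:00"),
                          tz = "UTC"),
       end = as.POSIXct(paste0(year, "-", cfg$season_end, " 23:59:59"),
                        tz = "UTC"))
}

#' Thin relocations to a minimum time interval
#'
#' Per animal: drops fixes outside the May-September season, collapses
#' exact-duplicate timestamps to one fix, then keeps fixes by a greedy
#' forward pass so successive retained fixes are at least `min_interval_h`
#' apart. The pass starts from a seed-chosen fix within the first interval
#' (or from the first fix when `seed` is `NULL`). With `max_speed` set,
#' fixes implying an implausible speed from the last kept fix are skipped.
#'
#' @param raw relocation data.frame (`animal_id`, `sex`, `year`,
#'   `timestamp` POSIXct, `x`, `y`).
#' @param cfg a [windowing_config()].
#' @param seed optional integer seed for the random starting fix.
#' @return thinned relocation data.frame, sorted by animal then time, with
#'   strictly increasing timestamps per animal.
#' @export
thin_relocations <- function(raw, cfg = windowing_config(), seed = NULL) {
  if (!inherits(raw$timestamp, "POSIXct")) {
    ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    bad <- which(is.na(ts) & !is.na(raw$timestamp))
    if (length(bad) > 0)
      stop("unparseable timestamp at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    raw$timestamp <- ts
  }
  if (!is.null(seed)) set.seed(seed)
  yrs <- as.integer(format(raw$timestamp, "%Y"))
  keep_season <- rep(FALSE, nrow(raw))
  for (y in unique(yrs)) {
    b <- season_bounds(cfg, y)
    keep_season <- keep_season |
      (yrs == y & raw$timestamp >= b$start & raw$timestamp <= b$end)
  }
  raw <- raw[keep_season, , drop = FALSE]
  if (nrow(raw) == 0) return(raw)
  raw <- raw[order(raw$animal_id, raw$timestamp), , drop = FALSE]
  min_gap <- cfg$min_interval_h * 3600
  pieces <- lapply(split(raw, raw$animal_id), function(d) {
    d <- d[!duplicated(d$timestamp), , drop = FALSE]
    n <- nrow(d)
    if (n == 0) return(d[0, , drop = FALSE])
    t <- as.numeric(d$timestamp)
    first_window <- which(t < t[1] + min_gap)
    start <- if (is.null(seed)) 1L else sample(first_window, 1L)
    keep <- logical(n); any_kept <- FALSE
    last <- -Inf; lastxy <- c(NA_real_, NA_real_)
    for (i in start:n) {
      if (any_kept && t[i] - last < min_gap) next
      if (any_kept && !is.null(cfg$max_speed)) {
        v <- sqrt((d$x[i] - lastxy[1])^2 + (d$y[i] - lastxy[2])^2) /
          ((t[i] - last) / 3600)
        if (v > cfg$max_speed) next
      }
      keep[i] <- TRUE; any_kept <- TRUE
      last <- t[i]; lastxy <- c(d$x[i], d$y[i])
    }
    d[keep, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Split a thinned relocation table into temporal windows
#'
#' Monthly windows are calendar months; biweekly and weekly windows are
#' consecutive 14- or 7-day blocks anchored at the season start of each
#' year. Partial trailing blocks are kept (flagged) if they meet the
#' minimum-location rule; windows with fewer than `min_locations` fixes are
#' dropped and logged in the `"dropped"` attribute.
#'
#' @param table thinned relocation data.frame.
#' @param cfg a [windowing_config()].
#' @return list of window records, each a list with `animal_id`, `window`
#'   (id like `"2006-M05"`), `scheme`, `partial` flag and `data`
#'   (the sub-table); attribute `"dropped"` is a data.frame of dropped
#'   windows with their fix counts.
#' @export
make_windows <- function(table, cfg = windowing_config()) {
  if (nrow(table) == 0)
    return(structure(list(), dropped = data.frame()))
  yrs <- as.integer(format(table$timestamp, "%Y"))
  ids <- character(nrow(table)); partial_ids <- character(0)
  for (y in unique(yrs)) {
    sel <- yrs == y
    b <- season_bounds(cfg, y)
    if (cfg$scheme == "monthly") {
      ids[sel] <- paste0(y, "-M", format(table$timestamp[sel], "%m"))
    } else {
      len_days <- if (cfg$scheme == "biweekly") 14 else 7
      blk <- floor(as.numeric(difftime(table$timestamp[sel], b$start,
                                       units = "days")) / len_days) + 1L
      tag <- if (cfg$scheme == "biweekly") "B" else "W"
      ids[sel] <- sprintf("%d-%s%02d", y, tag, blk)
      season_days <- as.numeric(difftime(b$end, b$start, units = "days"))
      lastfull <- floor(season_days / len_days)
      if (max(blk) > lastfull)
        partial_ids <- c(partial_ids,
                         sprintf("%d-%s%02d", y, tag,
                                 seq.int(lastfull + 1L, max(blk))))
    }
  }
  key <- paste(table$animal_id, ids, sep = "|")
  groups <- split(seq_len(nrow(table)), key)
  out <- list(); dropped <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    rec <- list(animal_id = parts[1], window = parts[2], scheme = cfg$scheme,
                partial = parts[2] %in% partial_ids,
                data = table[idx, , drop = FALSE])
    if (length(idx) < cfg$min_locations) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(animal_id = parts[1], window = parts[2],
                   n = length(idx))
    } else out[[length(out) + 1L]] <- rec
  }
  structure(out, dropped = if (length(dropped) > 0) do.call(rbind, dropped)
            else data.frame())
}

#' Reference bandwidth for the fixed-kernel estimator
#'
#' The bivariate-normal reference ("ad hoc") smoothing factor in the
#' convention of the classic home-range packages:
#' `h = 0.5 * (sd_x + sd_y) * n^(-1/6)`.
#'
#' @param x,y relocation coordinates in metres (or `x` a two-column
#'   matrix/data.frame).
#' @return bandwidth `h` in metres.
#' @export
reference_bandwidth <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  if (n < 5) stop("need at least 5 locations to estimate a bandwidth")
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  if (sdx == 0 && sdy == 0)
    stop("degenerate dispersion: all locations identical")
  0.5 * (sdx + sdy) * n^(-1 / 6)
}

#' Fixed-kernel utilization distribution
#'
#' Bivariate Gaussian kernel density with a single bandwidth, equal weight
#' per relocation, evaluated at cell centres of a regular grid covering the
#' points with a margin, then renormalized to integrate to 1 on the grid.
#'
#' @param x,y relocation coordinates (or `x` two-column).
#' @param h bandwidth in metres (default the reference bandwidth).
#' @param grid_res cell size in metres (default 30, matching the coarse
#'   imagery).
#' @param margin margin around the point bounding box in metres (default
#'   `5 * h`).
#' @return object of class `utilization_distribution`: `grid` (a
#'   `raster_grid` of densities), `h`, `n_points`.
#' @export
kernel_ud <- function(x, y = NULL, h = NULL, grid_res = 30, margin = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (is.null(h)) h <- reference_bandwidth(x, y)
  if (is.null(margin)) margin <- 5 * h
  xmin <- floor((min(x) - margin) / grid_res) * grid_res
  ymax <- ceiling((max(y) + margin) / grid_res) * grid_res
  nc <- ceiling((max(x) + margin - xmin) / grid_res)
  nr <- ceiling((ymax - (min(y) - margin)) / grid_res)
  gx <- xmin + (seq_len(nc) - 0.5) * grid_res
  gy <- ymax - (seq_len(nr) - 0.5) * grid_res
  # separable Gaussian: density = Gy %*% t(Gx) / n
  Gx <- vapply(x, function(xi) stats::dnorm(gx, xi, h), numeric(nc))
  Gy <- vapply(y, function(yi) stats::dnorm(gy, yi, h), numeric(nr))
  dens <- (Gy %*% t(Gx)) / length(x)
  cell_area <- grid_res^2
  dens <- dens / (sum(dens) * cell_area)
  structure(list(grid = raster_grid(dens, res = grid_res, xmin = xmin,
                                    ymax = ymax),
                 h = h, n_points = length(x)),
            class = "utilization_distribution")
}

#' @export
print.utilization_distribution <- function(x, ...) {
  cat(sprintf("utilization distribution: %d x %d cells at %g m, h = %.1f m, n = %d\n",
              rg_nrow(x$grid), rg_ncol(x$grid), x$grid$res, x$h, x$n_points))
  invisible(x)
}

#' Isopleth home range from a utilization distribution
#'
#' Sorts cells by density and takes the minimal prefix holding at least
#' `level`% of the probability mass: the smallest grid region containing
#' that share of the animal's space use. Area is the cell count times cell
#' area, reported in square kilometres.
#'
#' @param ud a [kernel_ud()] result.
#' @param level isopleth level in percent, in (0, 100); 50 is the
#'   conventional core area.
#' @param animal_id,window,scheme optional labels carried into the result.
#' @return object of class `home_range`: `level`, `area_km2`, `mask`
#'   (logical `raster_grid`), `polygons`, `n_points`, `h` plus the labels.
#' @export
isopleth <- function(ud, level, animal_id = NA_character_,
                     window = NA_character_, scheme = NA_character_) {
  stopifnot(inherits(ud, "utilization_distribution"),
            level > 0, level < 100)
  d <- rg_band(ud$grid)
  v <- as.vector(d)
  if (all(is.na(v)) || sum(v, na.rm = TRUE) == 0)
    stop("empty utilization distribution: no probability mass")
  cell_area <- ud$grid$res^2
  o <- order(v, decreasing = TRUE, na.last = TRUE)
  cum <- cumsum(v[o] * cell_area)
  ncells <- which(cum >= level / 100)[1]
  if (is.na(ncells)) ncells <- sum(!is.na(v))
  mask <- matrix(FALSE, nrow(d), ncol(d))
  mask[o[seq_len(ncells)]] <- TRUE
  mrast <- raster_grid(mask * 1, res = ud$grid$res, xmin = ud$grid$xmin,
                       ymax = ud$grid$ymax)
  structure(list(animal_id = animal_id, window = window, scheme = scheme,
                 level = level, area_km2 = ncells * cell_area / 1e6,
                 mask = mrast, polygons = mask_to_polygons(mrast),
                 n_points = ud$n_points, h = ud$h),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home range %s %s (%s): %g%% isopleth, %.3f km2 (n = %d, h = %.1f m)\n",
              x$animal_id, x$window, x$scheme, x$level, x$area_km2,
              x$n_points, x$h))
  invisible(x)
}

#' Estimate isopleth home ranges for all animals and windows
#'
#' Runs the full chain thin -> window -> kernel UD -> isopleths and returns
#' both the per-range records and a flat summary table.
#'
#' @param relocs raw relocation data.frame.
#' @param cfg a [windowing_config()].
#' @param levels isopleth levels in percent (default `c(50, 70, 90)`).
#' @param grid_res UD grid resolution in metres.
#' @param seed optional seed for the thinning start.
#' @param thin set `FALSE` if `relocs` is already thinned.
#' @return list with `ranges` (list of `home_range` objects), `table`
#'   (data.frame `animal_id,window,scheme,level,n_points,h,area_km2,partial`)
#'   and `dropped` (windows below the location minimum).
#' @export
estimate_home_ranges <- function(relocs, cfg = windowing_config(),
                                 levels = c(50, 70, 90), grid_res = 30,
                                 seed = NULL, thin = TRUE) {
  thinned <- if (thin) thin_relocations(relocs, cfg, seed) else relocs
  wins <- make_windows(thinned, cfg)
  ranges <- list(); rows <- list()
  for (w in wins) {
    ud <- kernel_ud(w$data$x, w$data$y, grid_res = grid_res)
    for (lv in levels) {
      hr <- isopleth(ud, lv, animal_id = w$animal_id, window = w$window,
                     scheme = w$scheme)
      hr$partial <- w$partial
      hr$sex <- w$data$sex[1]; hr$year <- w$data$year[1]
      ranges[[length(ranges) + 1L]] <- hr
      rows[[length(rows) + 1L]] <-
        data.frame(animal_id = w$animal_id, window = w$window,
                   scheme = w$scheme, level = lv, n_points = hr$n_points,
                   h = hr$h, area_km2 = hr$area_km2, partial = w$partial,
                   sex = hr$sex, year = hr$year)
    }
  }
  list(ranges = ranges,
       table = if (length(rows) > 0) do.call(rbind, rows) else data.frame(),
       dropped = attr(wins, "dropped"))
}
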