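#' Zonal statistics of a raster within a home range
#'
#' Mean, sample standard deviation (n - 1), variance and cell count of the
#' raster cells whose centres fall inside the home-range region. The raster
#' need not share the home-range grid: each raster cell centre is located in
#' the range mask.
#'
#' @param layer a `raster_grid` covering the range.
#' @param hr a `home_range` (or a logical-mask `raster_grid`).
#' @return list `mean`, `sd`, `variance`, `n_cells`.
#' @export
extract_stats <- function(layer, hr) {
  mask <- if (inherits(hr, "home_range")) hr$mask else hr
  cc <- rg_centers(layer)
  # restrict the scan to the mask's bounding box
  mx <- c(mask$xmin, mask$xmin + rg_ncol(mask) * mask$res)
  my <- c(mask$ymax - rg_nrow(mask) * mask$res, mask$ymax)
  ci <- which(cc$x >= mx[1] & cc$x <= mx[2])
  ri <- which(cc$y >= my[1] & cc$y <= my[2])
  if (length(ci) == 0 || length(ri) == 0)
    stop("no valid raster cells inside home range ",
         if (inherits(hr, "home_range"))
           paste(hr$animal_id, hr$window) else "")
  xs <- rep(cc$x[ci], each = length(ri))
  ys <- rep(cc$y[ri], times = length(ci))
  inside <- rg_extract(mask, xs, ys)
  v <- as.vector(rg_band(layer)[ri, ci, drop = FALSE])
  v <- v[!is.na(inside) & inside == 1]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop("no valid raster cells inside home range ",
         if (inherits(hr, "home_range"))
           paste(hr$animal_id, hr$window) else "")
  s <- if (length(v) > 1) stats::sd(v) else 0
  list(mean = mean(v), sd = s, variance = s^2, n_cells = length(v))
}

#' Assemble the per-home-range covariate table
#'
#' One row per estimated home range: log area plus the landscape covariates
#' used by the habitat model (mean and standard deviation of percent forest
#' cover, mean texture, mean elevation) and the grouping variables.
#'
#' @param hr_result result of [estimate_home_ranges()].
#' @param forest forest fractional-cover `raster_grid` (percent).
#' @param texture texture `raster_grid` (e.g. the contrast map).
#' @param dem elevation `raster_grid`.
#' @return data.frame with columns `animal_id, window, scheme, level,
#'   n_points, area_km2, log_area, mean_fc, sd_fc, texture, elevation,
#'   sex, year`. Areas are natural-log transformed.
#' @export
build_covariate_table <- function(hr_result, forest, texture, dem) {
  rows <- lapply(hr_result$ranges, function(hr) {
    fc <- extract_stats(forest, hr)
    tx <- extract_stats(texture, hr)
    el <- extract_stats(dem, hr)
    data.frame(animal_id = hr$animal_id, window = hr$window,
               scheme = hr$scheme, level = hr$level, n_points = hr$n_points,
               area_km2 = hr$area_km2, log_area = log(hr$area_km2),
               mean_fc = fc$mean, sd_fc = fc$sd, texture = tx$mean,
               elevation = el$mean, sex = hr$sex %||% NA_character_,
               year = hr$year %||% NA_integer_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise collinearity screen
#'
#' Computes the Pearson correlation matrix of candidate covariates and, for
#' every pair with `|r|` above the threshold, drops the variable that comes
#' later in the priority order (so e.g. the standard deviation of a layer is
#' kept over its variance).
#'
#' @param table covariate data.frame.
#' @param vars candidate variable names, in priority order (defaults to the
#'   model covariates plus `variance` when present).
#' @param threshold absolute Pearson correlation above which a pair is
#'   collinear (default 0.7).
#' @return list `kept`, `dropped` (data.frame of drop decisions) and
#'   `correlation` (the full matrix).
#' @export
collinearity_screen <- function(table, vars = NULL, threshold = 0.7) {
  if (is.null(vars))
    vars <- intersect(c("mean_fc", "sd_fc", "texture", "elevation",
                        "variance"), names(table))
  stopifnot(length(vars) >= 2, nrow(table) >= 3)
  cm <- stats::cor(table[, vars], use = "pairwise.complete.obs")
  kept <- vars; dropped <- list()
  for (a in seq_along(vars)) for (b in seq_along(vars)) {
    if (b <= a) next
    if (!(vars[a] %in% kept) || !(vars[b] %in% kept)) next
    if (abs(cm[a, b]) > threshold) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(dropped = vars[b], against = vars[a], r = cm[a, b])
      kept <- setdiff(kept, vars[b])
    }
  }
  list(kept = kept,
       dropped = if (length(dropped) > 0) do.call(rbind, dropped)
                 else data.frame(),
       correlation = cm)
}
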