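#' Gray-level co-occurrence configuration
#'
#' Controls quantization and the co-occurrence geometry for the Haralick
#' texture metrics. The window is fixed at 3x3 (each pixel against its eight
#' direct neighbours); co-occurrences are accumulated symmetrically over the
#' four unique direction offsets at distance 1 and pooled into one
#' direction-invariant matrix.
#'
#' @param n_levels number of quantization bins (default 16) over a fixed
#'   value range.
#' @param range value range quantized (default `c(0, 100)`, the percent-cover
#'   scale, so texture is comparable across home ranges).
#' @param metrics metrics computed by [texture_map()].
#' @param min_valid_pairs minimum valid (non-nodata) unordered pixel pairs in
#'   a window; below this the output pixel is nodata.
#' @return object of class `glcm_config`.
#' @export
glcm_config <- function(n_levels = 16L, range = c(0, 100),
                        metrics = c("contrast", "homogeneity",
                                    "dissimilarity", "entropy",
                                    "angular_second_moment", "correlation"),
                        min_valid_pairs = 4L) {
  stopifnot(n_levels >= 2, length(range) == 2, range[1] < range[2])
  structure(list(n_levels = as.integer(n_levels), range = range,
                 metrics = metrics,
                 min_valid_pairs = as.integer(min_valid_pairs),
                 offsets = rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))),
            class = "glcm_config")
}

#' Quantize a raster to integer gray levels
#'
#' Equal-width bins over a fixed range; values at the top edge fall in the
#' highest bin, values outside the range are clamped, nodata is preserved.
#'
#' @param raster a `raster_grid` (first band used).
#' @param n_levels number of bins.
#' @param range value range to bin (default `c(0, 100)`).
#' @return `raster_grid` of integer levels `0 .. n_levels - 1`.
#' @export
quantize <- function(raster, n_levels = 16L, range = c(0, 100)) {
  v <- rg_band(raster)
  lv <- floor((v - range[1]) / (range[2] - range[1]) * n_levels)
  lv <- pmin(pmax(lv, 0), n_levels - 1)
  raster_grid(lv, res = raster$res, xmin = raster$xmin, ymax = raster$ymax,
              crs = raster$crs)
}

# ordered within-window pair index table for a 3x3 patch (column-major
# indices 1..9) at the configured offsets, both directions
window_pairs <- function(cfg) {
  idx <- matrix(seq_len(9), 3, 3)
  ia <- integer(0); ib <- integer(0)
  for (o in seq_len(nrow(cfg$offsets))) {
    dr <- cfg$offsets[o, 1]; dc <- cfg$offsets[o, 2]
    for (r in 1:3) for (c in 1:3) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= 3 && c2 >= 1 && c2 <= 3) {
        ia <- c(ia, idx[r, c], idx[r2, c2])
        ib <- c(ib, idx[r2, c2], idx[r, c])
      }
    }
  }
  cbind(ia, ib)
}

#' Co-occurrence matrix of one 3x3 patch
#'
#' Counts level pairs over all in-patch pixel pairs at the configured
#' offsets, in both directions (symmetric accumulation), and normalizes to
#' sum 1. Pairs touching nodata are skipped; with fewer than
#' `min_valid_pairs` valid pairs the result is `NULL`.
#'
#' @param patch 3x3 integer matrix of gray levels (`NA` = nodata).
#' @param cfg a [glcm_config()].
#' @return `n_levels` x `n_levels` normalized co-occurrence matrix, or
#'   `NULL` for an insufficiently valid patch.
#' @export
glcm_window <- function(patch, cfg = glcm_config()) {
  stopifnot(all(dim(patch) == c(3, 3)))
  pr <- window_pairs(cfg)
  a <- patch[pr[, 1]]; b <- patch[pr[, 2]]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2 * cfg$min_valid_pairs) return(NULL)
  n <- cfg$n_levels
  counts <- tabulate(a[ok] * n + b[ok] + 1L, nbins = n * n)
  matrix(counts / sum(counts), n, n, byrow = TRUE)
}

#' Haralick metrics of a normalized co-occurrence matrix
#'
#' `haralick_contrast(p)` is the classic local-variation measure
#' `sum_(i,j) (i - j)^2 p(i,j)`; `haralick_metric` computes any of the six
#' supported metrics. For `correlation`, a degenerate matrix (zero marginal
#' variance, e.g. a constant patch) returns 0 by convention.
#'
#' @param p normalized co-occurrence matrix.
#' @param metric one of `contrast`, `homogeneity`, `dissimilarity`,
#'   `entropy`, `angular_second_moment`, `correlation`.
#' @return scalar metric value.
#' @export
haralick_metric <- function(p, metric) {
  n <- nrow(p)
  i <- matrix(0:(n - 1), n, n)          # row level
  j <- t(i)                              # col level
  switch(metric,
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    homogeneity = sum(p / (1 + (i - j)^2)),
    entropy = { q <- p[p > 0]; -sum(q * log(q)) },
    angular_second_moment = sum(p^2),
    correlation = {
      pi_ <- rowSums(p); pj <- colSums(p)
      mu_i <- sum((0:(n - 1)) * pi_); mu_j <- sum((0:(n - 1)) * pj)
      s_i <- sqrt(sum((0:(n - 1) - mu_i)^2 * pi_))
      s_j <- sqrt(sum((0:(n - 1) - mu_j)^2 * pj))
      if (s_i == 0 || s_j == 0) 0
      else sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
    },
    stop("unknown metric: ", metric))
}

#' @rdname haralick_metric
#' @export
haralick_contrast <- function(p) haralick_metric(p, "contrast")

#' Moving-window texture maps
#'
#' Computes each configured Haralick metric for every pixel from the
#' co-occurrence matrix of its 3x3 neighbourhood. Edge pixels (incomplete
#' neighbourhood) are nodata.
#'
#' @param raster a `raster_grid`; quantized with [quantize()] first unless
#'   `quantized = TRUE` already holds integer levels.
#' @param cfg a [glcm_config()].
#' @param quantized set `TRUE` if `raster` already contains integer levels.
#' @return named list of `raster_grid`s, one per metric.
#' @export
texture_map <- function(raster, cfg = glcm_config(), quantized = FALSE) {
  q <- if (quantized) raster else quantize(raster, cfg$n_levels, cfg$range)
  lv <- rg_band(q)
  nr <- nrow(lv); nc <- ncol(lv)
  n <- cfg$n_levels
  pr <- window_pairs(cfg)
  i <- matrix(0:(n - 1), n, n); j <- t(i)
  w_contrast <- (i - j)^2; w_dissim <- abs(i - j)
  w_homog <- 1 / (1 + (i - j)^2)
  lev <- 0:(n - 1)
  out <- lapply(cfg$metrics, function(m) matrix(NA_real_, nr, nc))
  names(out) <- cfg$metrics
  if (nr >= 3 && nc >= 3) {
    for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
      patch <- lv[(r - 1):(r + 1), (c - 1):(c + 1)]
      a <- patch[pr[, 1]]; b <- patch[pr[, 2]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2 * cfg$min_valid_pairs) next
      counts <- tabulate(a[ok] * n + b[ok] + 1L, nbins = n * n)
      p <- matrix(counts / sum(counts), n, n, byrow = TRUE)
      for (m in cfg$metrics) {
        out[[m]][r, c] <- switch(m,
          contrast = sum(w_contrast * p),
          dissimilarity = sum(w_dissim * p),
          homogeneity = sum(w_homog * p),
          entropy = { pp <- p[p > 0]; -sum(pp * log(pp)) },
          angular_second_moment = sum(p^2),
          correlation = {
            pi_ <- rowSums(p); pj <- colSums(p)
            mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
            s_i <- sqrt(sum((lev - mu_i)^2 * pi_))
            s_j <- sqrt(sum((lev - mu_j)^2 * pj))
            if (s_i == 0 || s_j == 0) 0
            else sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
          })
      }
    }
  }
  lapply(out, function(m)
    raster_grid(m, res = q$res, xmin = q$xmin, ymax = q$ymax, crs = q$crs))
}

#' Mean texture within a home range
#'
#' Averages the texture cells whose centres fall inside the home-range
#' region (cell-centre-in-mask rule, equivalent to point-in-polygon up to
#' grid discretization).
#'
#' @param tex texture `raster_grid`.
#' @param hr a `home_range`.
#' @return list with `mean` and `n_cells` (contributing cell count).
#' @export
mean_texture_in_range <- function(tex, hr) {
  st <- extract_stats(tex, hr)
  list(mean = st$mean, n_cells = st$n_cells)
}

#' Buffer-based size-dependency screen for texture metrics
#'
#' Averages each texture metric within circular buffers of increasing radius
#' around home-range centres and scores each metric's size dependency as the
#' mean (over centres) coefficient of variation of its radius profile; a low
#' score means the metric is stable in buffer size. This reproduces the
#' screen used to justify choosing contrast.
#'
#' @param tex_maps named list of texture `raster_grid`s (per metric).
#' @param centers two-column matrix/data.frame of centre coordinates
#'   (conventionally the 90% isopleth home-range centres).
#' @param radii buffer radii in metres (default 500-7000 m in 500 m steps).
#' @return list with `profile` (data.frame
#'   `metric,radius_m,center_id,mean_value`) and `scores` (data.frame
#'   `metric,score`, ascending: least size-dependent first).
#' @export
size_dependency_screen <- function(tex_maps, centers,
                                   radii = seq(500, 7000, by = 500)) {
  stopifnot(all(diff(radii) > 0))
  centers <- as.matrix(centers)
  rows <- list()
  for (m in names(tex_maps)) {
    r <- tex_maps[[m]]
    cc <- rg_centers(r)
    v <- rg_band(r)
    for (ci in seq_len(nrow(centers))) {
      d2 <- outer((cc$y - centers[ci, 2])^2, (cc$x - centers[ci, 1])^2, "+")
      for (rad in radii) {
        vals <- v[d2 <= rad^2]
        vals <- vals[!is.na(vals)]
        rows[[length(rows) + 1L]] <-
          data.frame(metric = m, radius_m = rad, center_id = ci,
                     mean_value = if (length(vals) > 0) mean(vals)
                                  else NA_real_)
      }
    }
  }
  profile <- do.call(rbind, rows)
  cv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || stats::sd(x) == 0) return(0)
    stats::sd(x) / abs(mean(x))
  }
  sc <- vapply(names(tex_maps), function(m) {
    sub <- profile[profile$metric == m, ]
    mean(vapply(split(sub$mean_value, sub$center_id), cv, numeric(1)))
  }, numeric(1))
  scores <- data.frame(metric = names(sc), score = unname(sc))
  scores <- scores[order(scores$score), ]
  rownames(scores) <- NULL
  list(profile = profile, scores = scores)
}
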