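#' Per-class fractional-cover stack
#'
#' A set of percent-cover layers (0-100) on the coarse grid, one per
#' land-cover class, constrained to sum to 100 over classes in every valid
#' pixel.
#'
#' @param layers named list of single-band `raster_grid`s, one per class.
#' @param provenance `"aggregated-truth"` (exact sub-pixel aggregation) or
#'   `"predicted"` (ensemble prediction).
#' @param diagnostics optional named list of extra layers (e.g. the
#'   pre-normalization pixel sums of a predicted stack).
#' @return object of class `fraction_stack`.
#' @export
fraction_stack <- function(layers, provenance = c("aggregated-truth",
                                                  "predicted"),
                           diagnostics = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            all(vapply(layers, is_raster_grid, logical(1))))
  structure(list(layers = layers, classes = names(layers),
                 provenance = provenance, diagnostics = diagnostics),
            class = "fraction_stack")
}

#' @export
print.fraction_stack <- function(x, ...) {
  cat(sprintf("fraction_stack (%s): classes %s, %d x %d coarse cells\n",
              x$provenance, paste(x$classes, collapse = "/"),
              rg_nrow(x$layers[[1]]), rg_ncol(x$layers[[1]])))
  invisible(x)
}

#' Regroup the codes of a categorical raster
#'
#' Maps each fine land-cover code to a superclass (e.g. 26 photo-interpreted
#' classes down to forest / open / other). Every code present in the raster
#' must appear in the mapping.
#'
#' @param fine categorical `raster_grid`.
#' @param mapping either a named character vector (names = fine class labels
#'   or codes, values = superclass labels) or a two-column data.frame
#'   `fine_code,superclass`.
#' @return categorical `raster_grid` over the superclasses; superclass order
#'   follows first appearance in the mapping.
#' @export
regroup_classes <- function(fine, mapping) {
  stopifnot(is_raster_grid(fine))
  if (is.data.frame(mapping)) {
    map <- stats::setNames(as.character(mapping[[2]]),
                           as.character(mapping[[1]]))
  } else map <- mapping
  codes <- rg_band(fine)
  keys <- if (!is.null(fine$levels)) fine$levels[codes] else as.character(codes)
  present <- unique(keys[!is.na(keys)])
  missing_codes <- setdiff(present, names(map))
  if (length(missing_codes) > 0)
    stop("class mapping is missing code(s): ",
         paste(missing_codes, collapse = ", "))
  superclasses <- unique(unname(map))
  newcodes <- matrix(match(map[keys], superclasses), nrow(codes), ncol(codes))
  raster_grid(newcodes, res = fine$res, xmin = fine$xmin, ymax = fine$ymax,
              crs = fine$crs, levels = superclasses)
}

#' Sub-pixel aggregation of a categorical map to fractional cover
#'
#' For each coarse cell (a `factor` x `factor` block of fine cells) computes
#' the percentage of fine cells in each class. Counting is exact, so the
#' per-pixel class percentages sum to exactly 100.
#'
#' @param fine categorical `raster_grid`.
#' @param factor integer aggregation factor; the fine extent must be
#'   divisible by it (no silent cropping).
#' @return a [fraction_stack] with provenance `"aggregated-truth"`.
#' @export
aggregate_fractions <- function(fine, factor) {
  stopifnot(is_raster_grid(fine), factor >= 1)
  codes <- rg_band(fine)
  nr <- nrow(codes); nc <- ncol(codes)
  if (nr %% factor != 0 || nc %% factor != 0)
    stop("fine extent ", nr, "x", nc, " is not divisible by factor ", factor)
  classes <- fine$levels %||% as.character(sort(unique(as.vector(codes))))
  code_vals <- if (is.null(fine$levels)) as.numeric(classes)
               else seq_along(classes)
  block_sum <- function(ind) {
    # sum over factor x factor blocks: fold rows, then columns
    m <- rowsum(ind, rep(seq_len(nr / factor), each = factor))
    t(rowsum(t(m), rep(seq_len(nc / factor), each = factor)))
  }
  coarse_res <- fine$res * factor
  layers <- lapply(seq_along(classes), function(k) {
    ind <- matrix(as.numeric(codes == code_vals[k]), nr, nc)
    raster_grid(block_sum(ind) * 100 / factor^2, res = coarse_res,
                xmin = fine$xmin, ymax = fine$ymax, crs = fine$crs)
  })
  names(layers) <- classes
  fraction_stack(layers, provenance = "aggregated-truth")
}

#' Ensemble configuration for the fraction model
#'
#' @param n_trees number of regression trees (default 1000).
#' @param predictors_per_split predictors tried per split; default
#'   `max(1, floor(n_bands / 3))`, filled in at fit time when `NULL`.
#' @param max_training_pixels optional cap on training pixels; when the
#'   aggregated-truth map has more valid pixels, a seeded simple random
#'   sample of this size is used (the usual practice when training data is
#'   wall-to-wall rather than a field sample).
#' @param seed integer RNG seed.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 1000L, predictors_per_split = NULL,
                            max_training_pixels = NULL, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 predictors_per_split = predictors_per_split,
                 max_training_pixels = max_training_pixels,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# flatten a multiband raster into a predictor data.frame; keeps complete rows
spectra_frame <- function(spectra) {
  nb <- rg_nband(spectra)
  df <- as.data.frame(lapply(seq_len(nb),
                             function(b) as.vector(rg_band(spectra, b))))
  names(df) <- paste0("band", seq_len(nb))
  df
}

#' Fit a regression-tree ensemble from spectra to percent cover
#'
#' Trains a random-forest regression of one class's percent cover (from the
#' aggregated-truth stack) on the coarse pixel band values, and reports
#' out-of-bag accuracy: variance explained as
#' `100 * (1 - OOB-MSE / var(y))` and OOB RMSE, both computed purely from
#' out-of-bag predictions.
#'
#' @param spectra multiband `raster_grid` on the coarse grid.
#' @param truth a [fraction_stack] on the same grid.
#' @param cfg an [ensemble_config()].
#' @param target_class class whose cover is modelled (e.g. `"forest"`).
#' @return list with elements `model` (the fitted `randomForest`) and
#'   `report` (class `fraction_model_report`: `oob_var_explained`,
#'   `oob_rmse`, `n_training_pixels`, `target_class`).
#' @export
fit_fraction_model <- function(spectra, truth, cfg = ensemble_config(),
                               target_class) {
  stopifnot(is_raster_grid(spectra), inherits(truth, "fraction_stack"),
            target_class %in% truth$classes)
  tl <- truth$layers[[target_class]]
  if (rg_nrow(tl) != rg_nrow(spectra) || rg_ncol(tl) != rg_ncol(spectra))
    stop("spectra and truth are not on the same coarse grid")
  X <- spectra_frame(spectra)
  y <- as.vector(rg_band(tl))
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) < 50) stop("need at least 50 training pixels, got ", length(y))
  if (stats::var(y) == 0)
    stop("degenerate response: percent cover of '", target_class,
         "' is constant")
  mtry <- cfg$predictors_per_split %||% max(1L, floor(ncol(X) / 3))
  set.seed(cfg$seed)
  if (!is.null(cfg$max_training_pixels) &&
      length(y) > cfg$max_training_pixels) {
    keep <- sample.int(length(y), cfg$max_training_pixels)
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  rf <- randomForest::randomForest(x = X, y = y, ntree = cfg$n_trees,
                                   mtry = mtry, keep.forest = TRUE)
  oob <- rf$predicted                       # OOB predictions only
  mse <- mean((oob - y)^2)
  report <- structure(list(
    target_class = target_class,
    oob_var_explained = 100 * (1 - mse / mean((y - mean(y))^2)),
    oob_rmse = sqrt(mse),
    n_training_pixels = length(y),
    n_trees = cfg$n_trees, predictors_per_split = mtry),
    class = "fraction_model_report")
  list(model = rf, report = report)
}

#' @export
print.fraction_model_report <- function(x, ...) {
  cat(sprintf(paste0("fraction model ('%s'): %d trees, mtry %d, %d pixels\n",
                     "  OOB variance explained: %.2f%%   OOB RMSE: %.2f%% cover\n"),
              x$target_class, x$n_trees, x$predictors_per_split,
              x$n_training_pixels, x$oob_var_explained, x$oob_rmse))
  invisible(x)
}

#' Predict wall-to-wall fractional cover
#'
#' Applies one fitted model per class to a multiband image, clips each
#' prediction to [0, 100], then rescales every pixel so the class layers sum
#' to 100 (independent per-class regressions do not guarantee the closure
#' constraint on their own). The pre-normalization pixel sum is retained as
#' a diagnostic layer. Nodata pixels in the spectra propagate to every
#' output layer.
#'
#' @param models named list (one entry per class) of fitted models as
#'   returned by [fit_fraction_model()] (either the list or the bare model).
#' @param spectra multiband `raster_grid`.
#' @return a [fraction_stack] with provenance `"predicted"` and a
#'   `raw_sum` diagnostic layer.
#' @export
predict_fractions <- function(models, spectra) {
  stopifnot(is_raster_grid(spectra), !is.null(names(models)))
  classes <- names(models)
  X <- spectra_frame(spectra)
  ok <- stats::complete.cases(X)
  nr <- rg_nrow(spectra); nc <- rg_ncol(spectra)
  pred <- matrix(NA_real_, sum(ok), length(classes))
  for (k in seq_along(classes)) {
    m <- models[[k]]
    if (is.list(m) && !inherits(m, "randomForest")) m <- m$model
    if (is.null(m)) stop("no model supplied for class '", classes[k], "'")
    p <- stats::predict(m, X[ok, , drop = FALSE])
    pred[, k] <- pmin(pmax(as.numeric(p), 0), 100)
  }
  raw_sum <- rowSums(pred)
  scale <- ifelse(raw_sum > 0, 100 / raw_sum, NA_real_)
  norm <- pmin(pmax(pred * scale, 0), 100)       # guard float overshoot
  norm[is.na(scale), ] <- 100 / length(classes)  # all-zero pixel: even split
  layers <- lapply(seq_along(classes), function(k) {
    v <- rep(NA_real_, nr * nc); v[ok] <- norm[, k]
    raster_grid(matrix(v, nr, nc), res = spectra$res, xmin = spectra$xmin,
                ymax = spectra$ymax, crs = spectra$crs)
  })
  names(layers) <- classes
  sums <- rep(NA_real_, nr * nc); sums[ok] <- raw_sum
  diag <- raster_grid(matrix(sums, nr, nc), res = spectra$res,
                      xmin = spectra$xmin, ymax = spectra$ymax)
  fraction_stack(layers, provenance = "predicted",
                 diagnostics = list(raw_sum = diag))
}
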