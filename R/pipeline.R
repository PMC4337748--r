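#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates every stage end-to-end on synthetic data: landscape +
#' telemetry simulation, fractional-cover modelling, texture, home-range
#' estimation, covariate extraction and the mixed habitat model, writing a
#' deterministic artifact directory (`rasters/`, `homeranges/`, `tables/`,
#' `models/`, `manifest.json`). One global seed fans out to fixed per-stage
#' offsets so stages are independently reproducible; rerunning the same
#' configuration gives bit-identical artifacts for deterministic stages.
#'
#' @param config path to a YAML file or an equivalent nested list. Sections
#'   (all optional, with defaults): `simulate` (landscape/telemetry
#'   parameters), `fraccover` (`n_trees`), `homerange` (`schemes`, `levels`,
#'   `min_locations`, `grid_res`), `texture` (`n_levels`, `screen`),
#'   `model` (selection switches), plus top-level `seed` and `output_dir`.
#' @param output_dir overrides the configured output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results (`landscape`,
#'   `fractions`, `texture`, `home_ranges`, `covariates`, `models`,
#'   `manifest`, `output_dir`).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  unknown <- setdiff(names(config),
                     c("seed", "output_dir", "simulate", "fraccover",
                       "homerange", "texture", "extract", "model"))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  say <- function(...) if (!quiet) message(...)
  seed <- as.integer(config$seed %||% 1L)
  out <- output_dir %||% config$output_dir %||% tempfile("rangecover_run_")
  for (d in c("", "rasters", "homeranges", "tables", "models"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  sim <- config$simulate %||% list()
  lcfg <- landscape_config(
    fine_resolution = sim$fine_resolution %||% 5,
    aggregation_factor = sim$aggregation_factor %||% 6L,
    extent = unlist(sim$extent %||% c(360L, 360L)),
    class_proportions = unlist(sim$class_proportions %||%
                                 c(forest = 0.55, open = 0.35, other = 0.10)),
    correlation_length = sim$correlation_length %||% 300,
    seed = seed + 1L)
  say("simulate: fine land cover ", lcfg$extent[1], "x", lcfg$extent[2])
  fine <- simulate_fine_landcover(lcfg)
  spec <- spectral_model(noise_sd = sim$noise_sd %||% 0.01, seed = seed + 2L)
  coarse <- simulate_coarse_image(fine, lcfg, spec)
  dem <- simulate_dem(lcfg, min_elev = sim$min_elev %||% 600,
                      max_elev = sim$max_elev %||% 1450, seed = seed + 3L)

  say("fraccover: aggregate truth + ensemble per class")
  fc <- config$fraccover %||% list()
  truth <- aggregate_fractions(fine, lcfg$aggregation_factor)
  ecfg <- ensemble_config(n_trees = fc$n_trees %||% 1000L, seed = seed + 4L)
  models_fc <- lapply(truth$classes, function(cl)
    fit_fraction_model(coarse, truth, ecfg, cl))
  names(models_fc) <- truth$classes
  predicted <- predict_fractions(lapply(models_fc, `[[`, "model"), coarse)

  say("texture: GLCM maps on the forest fraction layer")
  txc <- config$texture %||% list()
  gcfg <- glcm_config(n_levels = txc$n_levels %||% 16L)
  do_screen <- isTRUE(txc$screen)
  tmaps <- texture_map(predicted$layers[["forest"]],
                       if (do_screen) gcfg
                       else glcm_config(n_levels = gcfg$n_levels,
                                        metrics = "contrast"))
  contrast <- tmaps[["contrast"]]

  hrc <- config$homerange %||% list()
  schemes <- unlist(hrc$schemes %||% c("monthly", "biweekly", "weekly"))
  levels <- unlist(hrc$levels %||% c(50, 70, 90))
  mcfg <- movement_config(
    n_animals = sim$n_animals %||% 10L,
    sex_ratio = sim$sex_ratio %||% 0.5,
    season = unlist(sim$season %||% c("2006-05-01", "2006-09-30")),
    fix_interval_h = sim$fix_interval_h %||% 1,
    center_dispersion = sim$center_dispersion %||% 1000,
    attraction_rate = sim$attraction_rate %||% 0.15,
    step_sd = sim$step_sd %||% 140,
    habitat_effect = sim$habitat_effect,
    seed = seed + 5L)
  say("simulate: telemetry for ", mcfg$n_animals, " animals")
  relocs <- simulate_relocations(mcfg,
                                 landscape = list(
                                   forest = predicted$layers[["forest"]],
                                   texture = contrast, dem = dem))

  say("homerange + extract: ", paste(schemes, collapse = "/"))
  hr_results <- list(); cov_tables <- list()
  for (sc in schemes) {
    wcfg <- windowing_config(scheme = sc,
                             min_locations = hrc$min_locations %||% 10L,
                             min_interval_h = hrc$min_interval_h %||% 1)
    hr <- estimate_home_ranges(relocs, wcfg, levels = levels,
                               grid_res = hrc$grid_res %||% 30,
                               seed = seed + 6L)
    hr_results[[sc]] <- hr
    if (nrow(hr$table) > 0)
      cov_tables[[sc]] <- build_covariate_table(
        hr, predicted$layers[["forest"]], contrast, dem)
  }
  covariates <- if (length(cov_tables) > 0) do.call(rbind, cov_tables)
                else data.frame()

  screen <- NULL
  if (do_screen && length(hr_results) > 0) {
    r90 <- Filter(function(h) h$level == 90, hr_results[[1]]$ranges)
    centers <- t(vapply(r90, function(h) {
      cc <- rg_centers(h$mask); m <- rg_band(h$mask) == 1
      c(mean(rep(cc$x, each = length(cc$y))[m]),
        mean(rep(cc$y, times = length(cc$x))[m]))
    }, numeric(2)))
    if (nrow(centers) > 0) screen <- size_dependency_screen(tmaps, centers)
  }

  say("model: mixed model per scale")
  mdl <- config$model %||% list()
  fits <- list()
  if (nrow(covariates) > 0) {
    for (sc in unique(covariates$scheme)) for (lv in unique(covariates$level)) {
      sub <- covariates[covariates$scheme == sc & covariates$level == lv, ]
      if (nrow(sub) < 10) next
      id <- paste0(sc, "_", lv)
      fits[[id]] <- tryCatch(
        habitat_model(sub,
                      select_random = !isTRUE(mdl$no_select),
                      select_fixed = !isTRUE(mdl$no_select)),
        error = function(e) { say("  scale ", id, " skipped: ",
                                  conditionMessage(e)); NULL })
    }
    fits <- Filter(Negate(is.null), fits)
  }

  # ---- write artifacts ------------------------------------------------
  write_raster(fine, file.path(out, "rasters", "fine_landcover"))
  write_raster(coarse, file.path(out, "rasters", "coarse_image"))
  write_raster(dem, file.path(out, "rasters", "dem"))
  for (cl in truth$classes) {
    write_raster(truth$layers[[cl]],
                 file.path(out, "rasters", paste0("truth_", cl)))
    write_raster(predicted$layers[[cl]],
                 file.path(out, "rasters", paste0("predicted_", cl)))
  }
  write_raster(contrast, file.path(out, "rasters", "texture_contrast"))
  write_relocations(relocs, file.path(out, "tables", "relocations.csv"))
  utils::write.csv(covariates, file.path(out, "tables", "covariates.csv"),
                   row.names = FALSE)
  for (sc in names(hr_results)) {
    hr <- hr_results[[sc]]
    if (nrow(hr$table) > 0) {
      utils::write.csv(hr$table,
                       file.path(out, "homeranges",
                                 paste0("homeranges_", sc, ".csv")),
                       row.names = FALSE)
      write_geojson(hr$ranges,
                    file.path(out, "homeranges",
                              paste0("isopleths_", sc, ".geojson")))
    }
  }
  oob <- lapply(models_fc, function(m) unclass(m$report))
  jsonlite::write_json(oob, file.path(out, "models", "fraction_oob.json"),
                       auto_unbox = TRUE, digits = NA)
  for (id in names(fits)) {
    f <- fits[[id]]
    jsonlite::write_json(list(
      scale = id, n = f$n, terms = f$terms, grouping = f$grouping,
      coefficients = as.list(stats::setNames(f$coefficients$estimate,
                                             rownames(f$coefficients))),
      se = as.list(stats::setNames(f$coefficients$se,
                                   rownames(f$coefficients))),
      t = as.list(stats::setNames(f$coefficients$t,
                                  rownames(f$coefficients))),
      varcor = as.list(f$varcor), aic = f$aic, logLik = f$logLik,
      explained_deviance = f$explained_deviance),
      file.path(out, "models", paste0("model_", id, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(screen)) {
    utils::write.csv(screen$profile,
                     file.path(out, "tables", "texture_screen_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(screen$scores,
                     file.path(out, "tables", "texture_screen_scores.csv"),
                     row.names = FALSE)
  }

  cfg_file <- file.path(out, "config.yaml")
  # the stored config omits the output location so that identical analyses
  # hash identically wherever they are run
  yaml::write_yaml(config[setdiff(names(config), "output_dir")], cfg_file)
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "rangecover",
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = seed,
    stage_seeds = list(landscape = seed + 1L, spectra = seed + 2L,
                       dem = seed + 3L, ensemble = seed + 4L,
                       telemetry = seed + 5L, thinning = seed + 6L),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(landscape = list(fine = fine, coarse = coarse, dem = dem,
                                  config = lcfg),
                 fractions = list(truth = truth, predicted = predicted,
                                  models = models_fc),
                 texture = tmaps, screen = screen, relocations = relocs,
                 home_ranges = hr_results, covariates = covariates,
                 models = fits, manifest = manifest, output_dir = out))
}

#' Build an inspection report from pipeline results
#'
#' Writes a markdown report plus PNG figures into the artifact directory:
#' the study-wide distribution of categorical versus continuous forest
#' cover, a categorical / fractional / texture panel for one home range,
#' and log home-range area against each retained covariate with the model
#' prediction curve, for every fitted scale.
#'
#' @param result list returned by [run_pipeline()].
#' @return invisibly, the report file path.
#' @export
make_report <- function(result) {
  out <- result$output_dir
  figdir <- file.path(out, "figures")
  dir.create(figdir, showWarnings = FALSE)
  lines <- c("# Pipeline report", "")

  # figure 1: categorical vs continuous forest representation
  f1 <- file.path(figdir, "fraction_histogram.png")
  grDevices::png(f1, width = 900, height = 450)
  graphics::par(mfrow = c(1, 2))
  fine <- result$landscape$fine
  counts <- table(factor(rg_band(fine), levels = seq_along(fine$levels),
                         labels = fine$levels))
  graphics::barplot(100 * counts / sum(counts), ylab = "% of fine cells",
                    main = "categorical map")
  graphics::hist(rg_band(result$fractions$predicted$layers[["forest"]]),
                 breaks = 20, xlab = "forest cover (%)", main =
                   "predicted forest fractional cover")
  grDevices::dev.off()
  lines <- c(lines, "![](figures/fraction_histogram.png)", "")

  # figure 2: one home range, categorical vs continuous vs texture
  ranges <- unlist(lapply(result$home_ranges, function(h) h$ranges),
                   recursive = FALSE)
  if (length(ranges) > 0) {
    hr <- ranges[[1]]
    f2 <- file.path(figdir, "home_range_panel.png")
    grDevices::png(f2, width = 900, height = 340)
    graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
    for (spec in list(list(r = result$fractions$predicted$layers[["forest"]],
                           t = "forest fraction (%)"),
                      list(r = result$texture[["contrast"]],
                           t = "texture (contrast)"),
                      list(r = result$landscape$dem, t = "elevation (m)"))) {
      graphics::image(t(rg_band(spec$r))[, rev(seq_len(rg_nrow(spec$r)))],
                      main = spec$t, axes = FALSE,
                      col = grDevices::hcl.colors(20, "viridis"))
    }
    grDevices::dev.off()
    lines <- c(lines,
               sprintf("Home range panel for %s %s (%g%% isopleth, %.2f km2):",
                       hr$animal_id, hr$window, hr$level, hr$area_km2),
               "", "![](figures/home_range_panel.png)", "")
  } else {
    lines <- c(lines, "No home ranges met the minimum-location rule;",
               "covariate and model figures omitted.", "")
  }

  # figure 3: covariate vs log area with prediction curves
  if (length(result$models) > 0) {
    lines <- c(lines, sprintf("Fitted scales: %s.",
                              paste(names(result$models), collapse = ", ")),
               "")
    f3 <- file.path(figdir, "covariate_effects.png")
    nfit <- length(result$models)
    grDevices::png(f3, width = 450 * min(nfit, 3),
                   height = 380 * ceiling(nfit / 3))
    graphics::par(mfrow = c(ceiling(nfit / 3), min(nfit, 3)))
    for (id in names(result$models)) {
      fit <- result$models[[id]]
      plot(fit, main = id)
    }
    grDevices::dev.off()
    lines <- c(lines, "![](figures/covariate_effects.png)", "")
    for (id in names(result$models)) {
      fit <- result$models[[id]]
      lines <- c(lines, sprintf("## %s", id),
                 sprintf("- n = %d, AIC = %.1f", fit$n, fit$aic),
                 sprintf("- retained: %s",
                         paste(fit$terms, collapse = ", ")),
                 if (nrow(fit$explained_deviance) > 0)
                   sprintf("- explained deviance: %s",
                           paste(sprintf("%s %.1f%%",
                                         fit$explained_deviance$term,
                                         fit$explained_deviance$explained_deviance),
                                 collapse = ", ")),
                 "")
    }
  } else {
    lines <- c(lines, "No scale had enough home ranges for a model fit.", "")
  }
  report <- file.path(out, "report.md")
  writeLines(lines, report)
  invisible(report)
}
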