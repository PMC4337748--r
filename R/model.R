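#' Linear mixed habitat model of log home-range area
#'
#' Fits and selects the mixed model of log home-range area (km2, natural
#' log) on the landscape covariates, following a two-phase procedure:
#' first the random-intercept structure is chosen among candidate groupings
#' by REML likelihood-ratio comparison and AIC, then fixed effects are
#' reduced by backward stepwise elimination on t-values (threshold
#' `|t| >= 2`, inclusive) under ML, and the selected model is refit by
#' REML. Texture and elevation enter with quadratic terms (hump-shaped
#' relationships); a linear term is never dropped while its quadratic term
#' survives. Covariates are z-scored before fitting for numerical
#' stability; coefficients are reported on the standardized scale and,
#' equivalently, per original unit (linear terms) / per squared centred
#' unit (quadratic terms).
#'
#' @param data covariate data.frame (one row per home range) with columns
#'   `log_area`, the covariates, and the grouping variables.
#' @param covariates linear covariate names (default
#'   `c("mean_fc", "sd_fc", "texture", "elevation")`).
#' @param quadratic covariates that also get a squared term (default
#'   `c("texture", "elevation")`).
#' @param random_candidates candidate random-intercept groupings, in
#'   retention priority order: the first is dropped last (default
#'   `c("animal_id", "sex", "year")`, individual first).
#' @param t_threshold |t| threshold for keeping a fixed effect (default 2,
#'   inclusive: a term with |t| exactly 2 is retained).
#' @param alpha significance level for the random-structure likelihood-ratio
#'   tests (default 0.05).
#' @param select_random,select_fixed disable either selection phase to fit
#'   the full structure/model.
#' @return object of class `habitat_model`; see [summary.habitat_model()].
#' @export
habitat_model <- function(data,
                          covariates = c("mean_fc", "sd_fc", "texture",
                                         "elevation"),
                          quadratic = c("texture", "elevation"),
                          random_candidates = c("animal_id", "sex", "year"),
                          t_threshold = 2, alpha = 0.05,
                          select_random = TRUE, select_fixed = TRUE) {
  stopifnot("log_area" %in% names(data), all(covariates %in% names(data)))
  data <- data[is.finite(data$log_area), , drop = FALSE]

  # standardized modelling frame
  scalers <- lapply(data[covariates], function(x)
    list(center = mean(x), scale = stats::sd(x)))
  frame <- data.frame(log_area = data$log_area)
  for (v in covariates) {
    s <- scalers[[v]]
    if (s$scale == 0) stop("covariate '", v, "' is constant")
    frame[[v]] <- (data[[v]] - s$center) / s$scale
  }
  terms <- covariates
  for (v in intersect(quadratic, covariates)) {
    frame[[paste0(v, "2")]] <- frame[[v]]^2
    terms <- c(terms, paste0(v, "2"))
  }
  for (g in random_candidates)
    if (g %in% names(data)) frame[[g]] <- factor(data[[g]])

  usable <- random_candidates[vapply(random_candidates, function(g)
    g %in% names(frame) && nlevels(frame[[g]]) >= 2, logical(1))]
  if (length(usable) == 0)
    stop("no candidate grouping has >= 2 levels; ",
         "fit a fixed-effects-only model instead (e.g. via lm)")

  grouping <- if (select_random)
    select_random_structure(frame, terms, usable, alpha = alpha)
  else usable

  sel <- if (select_fixed)
    backward_select_fixed(frame, terms, grouping, t_threshold = t_threshold)
  else list(terms = terms, trace = data.frame())

  final <- fit_mm(frame, sel$terms, grouping, REML = TRUE)
  ct <- coef_table(final)
  ed <- explained_deviance_internal(frame, sel$terms, grouping, covariates)

  # back-transform: linear terms per original unit, quadratic per squared
  # centred original unit
  co <- ct$estimate; names(co) <- rownames(ct)
  orig <- co
  for (v in covariates) {
    s <- scalers[[v]]
    if (v %in% names(orig)) orig[v] <- co[v] / s$scale
    q <- paste0(v, "2")
    if (q %in% names(orig)) orig[q] <- co[q] / s$scale^2
  }

  vc <- varcomp(final)
  structure(list(
    coefficients = ct, coefficients_original = orig,
    terms = sel$terms, grouping = grouping,
    varcor = vc, aic = stats::AIC(final),
    logLik = as.numeric(stats::logLik(final)),
    explained_deviance = ed, scalers = scalers,
    covariates = covariates, quadratic = quadratic,
    selection_trace = sel$trace, fit = final, frame = frame,
    n = nrow(frame)), class = "habitat_model")
}

# fit helper: lmer when groupings present, lm otherwise
fit_mm <- function(frame, terms, grouping, REML = TRUE) {
  rhs <- if (length(terms) > 0) paste(terms, collapse = " + ") else "1"
  if (length(grouping) > 0) {
    f <- stats::as.formula(paste("log_area ~", rhs, "+",
                                 paste(sprintf("(1 | %s)", grouping),
                                       collapse = " + ")))
    suppressMessages(lme4::lmer(f, data = frame, REML = REML,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore")))
  } else {
    stats::lm(stats::as.formula(paste("log_area ~", rhs)), data = frame)
  }
}

loglik_reml <- function(fit) {
  if (inherits(fit, "lm")) as.numeric(stats::logLik(fit, REML = TRUE))
  else as.numeric(stats::logLik(fit))
}

coef_table <- function(fit) {
  cs <- if (inherits(fit, "merMod")) stats::coef(summary(fit))
        else stats::coef(summary(fit))[, 1:3, drop = FALSE]
  out <- data.frame(estimate = cs[, 1], se = cs[, 2], t = cs[, 3])
  rownames(out) <- sub("^I\\((.*)\\)$", "\\1", rownames(cs))
  rownames(out)[rownames(out) == "(Intercept)"] <- "(Intercept)"
  out
}

varcomp <- function(fit) {
  if (!inherits(fit, "merMod"))
    return(c(residual = summary(fit)$sigma^2))
  vc <- lme4::VarCorr(fit)
  out <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  c(out, residual = attr(vc, "sc")^2)
}

#' Select the random-intercept structure
#'
#' Starts from the full set of candidate random intercepts (fit by REML
#' with the full fixed-effect formula) and simplifies backwards: a grouping
#' is removable when the likelihood-ratio test against the reduced model is
#' non-significant at `alpha` (or its variance component is singular);
#' among removable groupings the one whose removal gives the lowest REML
#' AIC is dropped, preferring to drop lower-priority groupings on ties.
#' Candidates are listed in retention priority order (first = dropped
#' last).
#'
#' @param frame modelling data.frame (standardized covariates).
#' @param terms fixed-effect term names.
#' @param candidates candidate grouping names present in `frame`.
#' @param alpha LRT significance level.
#' @return character vector of retained groupings (possibly empty).
#' @export
select_random_structure <- function(frame, terms, candidates, alpha = 0.05) {
  current <- candidates
  repeat {
    if (length(current) == 0) break
    full <- fit_mm(frame, terms, current, REML = TRUE)
    ll_full <- loglik_reml(full)
    aic_full <- stats::AIC(full)
    cand <- data.frame(g = current, p = NA_real_, aic = NA_real_,
                       singular = FALSE, stringsAsFactors = FALSE)
    for (k in seq_along(current)) {
      red <- fit_mm(frame, terms, setdiff(current, current[k]), REML = TRUE)
      stat <- max(0, 2 * (ll_full - loglik_reml(red)))
      # boundary-corrected LRT for a variance component
      cand$p[k] <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
      cand$aic[k] <- stats::AIC(red)
      if (inherits(full, "merMod")) {
        vc <- varcomp(full)
        cand$singular[k] <- vc[current[k]] < 1e-8
      }
    }
    removable <- which(cand$p >= alpha | cand$singular)
    if (length(removable) == 0) break
    # lowest AIC wins; ties go to dropping the lowest-priority grouping
    prio <- match(cand$g, candidates)
    ord <- removable[order(cand$aic[removable], -prio[removable])]
    best <- ord[1]
    if (cand$aic[best] > aic_full && !cand$singular[best]) break
    current <- setdiff(current, cand$g[best])
  }
  current
}

#' Backward stepwise fixed-effect selection on t-values
#'
#' Under ML, repeatedly drops the fixed-effect term with the smallest
#' `|t| < t_threshold` (threshold inclusive: `|t| = t_threshold` is kept),
#' never dropping a linear term whose quadratic partner survives, until all
#' remaining terms meet the threshold.
#'
#' @param frame modelling data.frame.
#' @param terms starting fixed-effect term names (quadratic terms named
#'   `<var>2`).
#' @param grouping retained random-intercept groupings.
#' @param t_threshold |t| threshold for retention.
#' @return list `terms` (retained) and `trace` (data.frame of drops with
#'   the |t| at removal).
#' @export
backward_select_fixed <- function(frame, terms, grouping, t_threshold = 2) {
  current <- terms
  trace <- list()
  repeat {
    fit <- fit_mm(frame, current, grouping, REML = FALSE)
    ct <- coef_table(fit)
    tv <- ct$t[match(current, rownames(ct))]
    protected <- vapply(current, function(tm)
      paste0(tm, "2") %in% current, logical(1))
    drop_ok <- !protected & abs(tv) < t_threshold
    if (!any(drop_ok)) break
    worst <- current[drop_ok][which.min(abs(tv[drop_ok]))]
    trace[[length(trace) + 1L]] <-
      data.frame(term = worst, t = tv[current == worst])
    current <- setdiff(current, worst)
  }
  list(terms = current,
       trace = if (length(trace) > 0) do.call(rbind, trace)
               else data.frame())
}

# per-variable drop-one explained deviance, ML fits for comparability:
# 100 * (dev(model without the variable) - dev(full)) / dev(null),
# where null = intercept + random effects and dev = -2 logLik (ML).
# Linear + quadratic terms of one covariate are pooled. Random groupings
# are scored analogously by removing the grouping.
explained_deviance_internal <- function(frame, terms, grouping, covariates) {
  dev_ml <- function(tms, grp)
    -2 * as.numeric(stats::logLik(fit_mm(frame, tms, grp, REML = FALSE)))
  d_full <- dev_ml(terms, grouping)
  d_null <- dev_ml(character(0), grouping)
  if (d_null <= 0) {
    warning("null deviance is non-positive; explained deviance undefined")
    return(data.frame())
  }
  rows <- list()
  for (v in covariates) {
    vterms <- intersect(c(v, paste0(v, "2")), terms)
    if (length(vterms) == 0) next
    d_wo <- dev_ml(setdiff(terms, vterms), grouping)
    rows[[length(rows) + 1L]] <-
      data.frame(term = v, type = "fixed",
                 explained_deviance = 100 * max(0, d_wo - d_full) / d_null)
  }
  for (g in grouping) {
    d_wo <- dev_ml(terms, setdiff(grouping, g))
    rows[[length(rows) + 1L]] <-
      data.frame(term = g, type = "random",
                 explained_deviance = 100 * max(0, d_wo - d_full) / d_null)
  }
  if (length(rows) > 0) do.call(rbind, rows) else data.frame()
}

#' Explained deviance of a fitted habitat model
#' @param fit a `habitat_model`.
#' @return data.frame `term, type, explained_deviance` (percent; drop-one
#'   deviance relative to the intercept-plus-random-effects model, ML fits).
#' @export
explained_deviance <- function(fit) {
  stopifnot(inherits(fit, "habitat_model"))
  fit$explained_deviance
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("Linear mixed habitat model of log home-range area\n")
  cat("  n =", x$n, " random intercepts:",
      if (length(x$grouping) > 0) paste(x$grouping, collapse = ", ")
      else "(none)", "\n")
  cat("  retained fixed effects:",
      if (length(x$terms) > 0) paste(x$terms, collapse = ", ") else "(none)",
      "\n")
  cat(sprintf("  AIC %.1f, logLik %.1f\n", x$aic, x$logLik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summary of a habitat model
#' @param object a `habitat_model`.
#' @param ... unused.
#' @return the object, invisibly, after printing coefficients (both
#'   scales), variance components and explained deviance.
#' @export
summary.habitat_model <- function(object, ...) {
  print(object)
  cat("\nCoefficients per original covariate unit:\n")
  print(round(object$coefficients_original, 6))
  cat("\nVariance components:\n")
  print(round(object$varcor, 5))
  if (nrow(object$explained_deviance) > 0) {
    cat("\nExplained deviance (%):\n")
    print(transform(object$explained_deviance,
                    explained_deviance = round(explained_deviance, 2)))
  }
  if (nrow(object$selection_trace) > 0) {
    cat("\nDropped during backward selection:\n")
    print(transform(object$selection_trace, t = round(t, 3)))
  }
  invisible(object)
}

#' @export
coef.habitat_model <- function(object, scale = c("standardized", "original"),
                               ...) {
  scale <- match.arg(scale)
  if (scale == "standardized")
    stats::setNames(object$coefficients$estimate,
                    rownames(object$coefficients))
  else object$coefficients_original
}

#' Predict log home-range area
#'
#' Evaluates the fixed-effect part of the model (population level, random
#' effects set to zero) for new covariate values on the original scale.
#'
#' @param object a `habitat_model`.
#' @param newdata data.frame with the model covariates (original units).
#' @param ... unused.
#' @return numeric vector of predicted log areas.
#' @export
predict.habitat_model <- function(object, newdata, ...) {
  nd <- data.frame(row.names = seq_len(nrow(newdata)))
  for (v in object$covariates) {
    s <- object$scalers[[v]]
    nd[[v]] <- (newdata[[v]] - s$center) / s$scale
    q <- paste0(v, "2")
    if (q %in% object$terms) nd[[q]] <- nd[[v]]^2
  }
  co <- stats::setNames(object$coefficients$estimate,
                        rownames(object$coefficients))
  out <- rep(co[["(Intercept)"]], nrow(nd))
  for (tm in object$terms) out <- out + co[[tm]] * nd[[tm]]
  out
}

#' @export
residuals.habitat_model <- function(object, ...) stats::residuals(object$fit)

#' Partial-effect plot of a habitat model
#'
#' Scatter of log area against one covariate with the model's fixed-effect
#' prediction curve (other covariates held at their means).
#'
#' @param x a `habitat_model`.
#' @param variable covariate to display (default the first retained one).
#' @param ... passed to [graphics::plot()].
#' @export
plot.habitat_model <- function(x, variable = NULL, ...) {
  lin <- intersect(x$covariates, x$terms)
  if (is.null(variable)) variable <- if (length(lin) > 0) lin[1]
                                     else x$covariates[1]
  obs_x <- x$frame[[variable]] * x$scalers[[variable]]$scale +
    x$scalers[[variable]]$center
  graphics::plot(obs_x, x$frame$log_area, xlab = variable,
                 ylab = "log home-range area (km2)", pch = 16,
                 col = grDevices::grey(0.4), ...)
  xs <- seq(min(obs_x), max(obs_x), length.out = 100)
  nd <- data.frame(lapply(x$covariates, function(v)
    rep(x$scalers[[v]]$center, 100)))
  names(nd) <- x$covariates
  nd[[variable]] <- xs
  graphics::lines(xs, predict(x, nd), lwd = 2)
  invisible(x)
}

#' Fit the habitat model at every spatio-temporal scale
#'
#' Splits a combined covariate table by temporal scheme and isopleth level
#' and fits the selected mixed model for each of the nine scales, returning
#' the fits plus a long summary of coefficients and explained deviance.
#'
#' @param table combined covariate data.frame with `scheme` and `level`
#'   columns.
#' @param schemes,levels the expected scales (all nine combinations must be
#'   present).
#' @param ... passed to [habitat_model()].
#' @return object of class `habitat_model_scales`: list with `fits` (named
#'   list) and `summary` (data.frame).
#' @export
run_all_scales <- function(table, schemes = c("monthly", "biweekly", "weekly"),
                           levels = c(50, 70, 90), ...) {
  fits <- list(); rows <- list()
  for (sc in schemes) for (lv in levels) {
    sub <- table[table$scheme == sc & table$level == lv, , drop = FALSE]
    id <- paste0(sc, "_", lv)
    if (nrow(sub) == 0)
      stop("no covariate rows for scale ", sc, " x ", lv, "%")
    fit <- habitat_model(sub, ...)
    fits[[id]] <- fit
    ed <- fit$explained_deviance
    for (tm in rownames(fit$coefficients)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = sc, level = lv, term = tm,
        estimate = fit$coefficients[tm, "estimate"],
        se = fit$coefficients[tm, "se"], t = fit$coefficients[tm, "t"],
        explained_deviance = if (nrow(ed) > 0 && tm %in% ed$term)
          ed$explained_deviance[match(tm, ed$term)] else NA_real_)
    }
  }
  structure(list(fits = fits, summary = do.call(rbind, rows)),
            class = "habitat_model_scales")
}

#' @export
print.habitat_model_scales <- function(x, ...) {
  cat("habitat models across", length(x$fits), "spatio-temporal scales\n")
  print(transform(x$summary, estimate = round(estimate, 4),
                  se = round(se, 4), t = round(t, 2),
                  explained_deviance = round(explained_deviance, 2)))
  invisible(x)
}
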