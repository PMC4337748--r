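# direct covariate-table simulator for model-level tests: n_animals with
# n_windows rows each, independent covariates, configurable true effects on
# the standardized scale
sim_table <- function(n_animals = 40, n_windows = 5, beta = list(),
                      id_sd = 0.3, resid_sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_animals * n_windows
  id <- rep(sprintf("A%02d", seq_len(n_animals)), each = n_windows)
  d <- data.frame(animal_id = id,
                  sex = rep(rep(c("F", "M"), length.out = n_animals),
                            each = n_windows),
                  year = rep(rep(2004:2006, length.out = n_animals),
                             each = n_windows),
                  scheme = "monthly", level = 90)
  d$mean_fc <- rnorm(n, 50, 10)
  d$sd_fc <- rnorm(n, 20, 5)
  d$texture <- rnorm(n, 10, 3)
  d$elevation <- rnorm(n, 900, 150)
  b <- rnorm(n_animals, 0, id_sd)[rep(seq_len(n_animals), each = n_windows)]
  lp <- 0.2 + b
  for (v in names(beta)) {
    base <- sub("2$", "", v)
    z <- as.numeric(scale(d[[base]]))
    lp <- lp + beta[[v]] * if (grepl("2$", v)) z^2 else z
  }
  d$log_area <- lp + rnorm(n, 0, resid_sd)
  d$area_km2 <- exp(d$log_area)
  d
}

test_that("random-structure selection keeps the dominant grouping only", {
  hits <- 0L
  for (r in 1:10) {
    d <- sim_table(n_animals = 30, beta = list(sd_fc = 0.3), id_sd = 0.6,
                   resid_sd = 0.3, seed = 100 + r)
    fit <- suppressWarnings(habitat_model(d))
    expect_true("animal_id" %in% fit$grouping)   # dominant grouping kept
    if (identical(fit$grouping, "animal_id")) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})

test_that("degenerate groupings are rejected with advice", {
  d <- sim_table(n_animals = 1, n_windows = 12, seed = 3)
  expect_error(habitat_model(d), "fixed-effects-only")
})

test_that("backward selection removes null terms and honours the hierarchy", {
  # null simulation smoke: surviving terms are rare (expected ~0.3 per
  # replicate for six terms at the |t| >= 2 threshold) and always meet the
  # threshold themselves
  survivors <- integer(10)
  for (r in 1:10) {
    d <- sim_table(seed = 200 + r)
    fit <- suppressWarnings(habitat_model(d))
    survivors[r] <- length(fit$terms)
    if (length(fit$terms) > 0) {
      tv <- fit$coefficients[fit$terms, "t"]
      protected <- vapply(fit$terms, function(tm)
        paste0(tm, "2") %in% fit$terms, logical(1))
      expect_true(all(abs(tv[!protected]) >= 2))
    }
  }
  expect_lt(mean(survivors), 1)

  # planted pure-quadratic texture effect: texture2 retained with its sign,
  # and the linear term is protected while its quadratic survives
  for (r in 1:5) {
    d <- sim_table(n_animals = 60, beta = list(texture2 = -0.4),
                   seed = 300 + r)
    fit <- habitat_model(d)
    expect_true("texture2" %in% fit$terms)
    expect_lt(fit$coefficients["texture2", "estimate"], 0)
    expect_true("texture" %in% fit$terms)
  }
})

test_that("the |t| threshold is inclusive at exactly 2", {
  d <- sim_table(n_animals = 40, beta = list(sd_fc = 0.5), seed = 7)
  frame <- data.frame(log_area = d$log_area,
                      sd_fc = as.numeric(scale(d$sd_fc)),
                      animal_id = factor(d$animal_id))
  sel <- backward_select_fixed(frame, "sd_fc", "animal_id",
                               t_threshold = 2)
  fit <- lme4::lmer(log_area ~ sd_fc + (1 | animal_id), data = frame,
                    REML = FALSE)
  tval <- coef(summary(fit))["sd_fc", "t value"]
  # set the threshold exactly at the observed |t|: inclusive, so retained
  sel_at <- backward_select_fixed(frame, "sd_fc", "animal_id",
                                  t_threshold = abs(tval))
  expect_true("sd_fc" %in% sel_at$terms)
  sel_above <- backward_select_fixed(frame, "sd_fc", "animal_id",
                                     t_threshold = abs(tval) + 1e-8)
  expect_false("sd_fc" %in% sel_above$terms)
})

test_that("explained deviance is deterministic, non-negative and ~0 for null terms", {
  d <- sim_table(n_animals = 40, beta = list(sd_fc = 0.5, texture2 = -0.3),
                 seed = 9)
  fit1 <- suppressWarnings(habitat_model(d, select_fixed = FALSE,
                                         select_random = FALSE))
  fit2 <- suppressWarnings(habitat_model(d, select_fixed = FALSE,
                                         select_random = FALSE))
  expect_identical(fit1$explained_deviance, fit2$explained_deviance)
  ed <- fit1$explained_deviance
  expect_true(all(ed$explained_deviance >= 0))
  # planted terms explain much more than null terms
  get <- function(v) ed$explained_deviance[ed$term == v]
  expect_gt(get("sd_fc"), get("mean_fc"))
  expect_gt(get("texture"), get("elevation"))
  nulls <- vapply(1:5, function(r) {
    dn <- sim_table(seed = 400 + r)
    fn <- suppressWarnings(habitat_model(dn, select_fixed = FALSE, select_random = FALSE))
    edn <- fn$explained_deviance
    edn$explained_deviance[edn$term == "mean_fc"]
  }, 0)
  expect_lt(median(nulls), 1)
})

test_that("refitting the selected model reproduces coefficients exactly", {
  d <- sim_table(n_animals = 30, beta = list(sd_fc = 0.4), seed = 13)
  f1 <- habitat_model(d)
  f2 <- habitat_model(d)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-10)
})

test_that("model methods are coherent: coef, predict, residuals, plot, print", {
  d <- sim_table(n_animals = 30, beta = list(sd_fc = 0.5), seed = 17)
  fit <- habitat_model(d)
  expect_output(print(fit), "retained fixed effects")
  expect_output(summary(fit), "Variance components")
  co <- coef(fit)
  expect_true("(Intercept)" %in% names(co))
  # predictions respond to the retained covariate in the planted direction
  nd <- d[1:2, ]; nd$sd_fc <- c(10, 30)
  pr <- predict(fit, nd)
  expect_gt(pr[2], pr[1])
  expect_length(residuals(fit), nrow(d))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("run_all_scales fits every scheme-level cell and summarizes it", {
  tabs <- do.call(rbind, lapply(c("monthly", "biweekly", "weekly"),
                                function(sc) {
    do.call(rbind, lapply(c(50, 70, 90), function(lv) {
      d <- sim_table(n_animals = 25, beta = list(sd_fc = 0.5),
                     seed = match(sc, c("monthly", "biweekly", "weekly")) *
                       100 + lv)
      d$scheme <- sc; d$level <- lv
      d
    }))
  }))
  res <- suppressWarnings(run_all_scales(tabs))
  expect_length(res$fits, 9)
  expect_true(all(c("scheme", "level", "term", "estimate", "t") %in%
                    names(res$summary)))
  expect_equal(nrow(res$summary),
               sum(vapply(res$fits, function(f) nrow(f$coefficients), 0L)))
  expect_error(suppressWarnings(run_all_scales(tabs[tabs$scheme != "weekly", ])),
               "weekly")
})
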