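pacli_control_data <- function(noise_cv = 0, seed = 7) {
  des <- casestudy_template("paclitaxel", noise_cv = noise_cv, seed = seed)
  st <- generate_study(des)
  list(data = st$observations[st$observations$arm == "control", ],
       spec = design_model_spec(des))
}

test_that("noiseless growth parameters are recovered to high precision", {
  x <- pacli_control_data()
  spec <- x$spec
  spec$growth$p0 <- 1.6; spec$growth$kin0 <- 0.08; spec$growth$wth <- 1.5
  fit <- fit_tgi_continuous(x$data, spec,
                            fit_config(free = c("p0", "kin0", "wth"),
                                       n_starts = 2))
  truth <- c(p0 = 1.44, kin0 = 4.04e-2, wth = 2.48)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-3)
  expect_lt(fit$ssr, 1e-12 * sum(x$data$volume^2))
  expect_true(fit$converged)
})

test_that("a dataset equal to the starting prediction yields zero SSR and ~0 CV%", {
  x <- pacli_control_data()
  spec <- x$spec
  pred <- simulate_tumor_growth(
    spec$growth, max(x$data$time_day), times = x$data$time_day)$w
  data <- x$data
  data$volume <- pred
  fit <- fit_tgi_continuous(data, spec,
                            fit_config(free = c("p0", "kin0"),
                                       n_starts = 1))
  expect_lt(fit$ssr, 1e-18)
  expect_lt(max(fit$cv_pct, na.rm = TRUE), 1e-3)
  # fixed parameters are carried through unchanged
  expect_equal(fit$fixed[["wth"]], 2.48)
  expect_equal(fit$fixed[["T"]], 1.46)
  expect_equal(fit$fixed[["w0"]], 0.033)
})

test_that("fit inputs are validated", {
  x <- pacli_control_data()
  expect_error(fit_tgi_continuous(x$data, x$spec, fit_config()),
               class = "lstgi_invalid")
  few <- x$data[1:2, ]
  expect_error(fit_tgi_continuous(few, x$spec,
                                  fit_config(free = c("p0", "kin0"))),
               class = "lstgi_invalid")
  bad <- x$data; bad$volume[1] <- -1
  expect_error(fit_tgi_continuous(bad, x$spec,
                                  fit_config(free = "p0")),
               class = "lstgi_invalid")
})

test_that("the lifespan grid returns the generating node on noiseless data", {
  x <- pacli_control_data()
  spec <- x$spec
  spec$growth$p0 <- 1.5; spec$growth$kin0 <- 0.05; spec$growth$wth <- 2
  spec$hmax <- spec$growth$T / 40
  cfg <- fit_config(free = c("p0", "kin0", "wth"),
                    grid_T = c(1.34, 1.40, 1.46, 1.52, 1.58),
                    refine = FALSE, n_starts = 1)
  gs <- grid_search_lifespans(x$data, spec, cfg, search = "T")
  expect_identical(gs$best_T, 1.46)
  # unique global minimum over the scanned profile
  expect_true(all(gs$trace$ssr[gs$trace$T != 1.46] >
                    min(gs$trace$ssr) + 1e-8))
  # single-node grid trivially returns that node, with its fit
  gs1 <- grid_search_lifespans(x$data, spec,
                               fit_config(free = c("p0", "kin0", "wth"),
                                          grid_T = 1.46, refine = FALSE,
                                          n_starts = 1), search = "T")
  expect_identical(gs1$best_T, 1.46)
  expect_equal(nrow(gs1$trace), 1L)
  # refinement can only improve (or preserve) the objective
  cfg_ref <- cfg
  cfg_ref$refine <- TRUE
  cfg_ref$fine_step <- 0.02
  gs_ref <- grid_search_lifespans(x$data, spec, cfg_ref, search = "T")
  expect_lte(gs_ref$best_fit$ssr, gs$best_fit$ssr + 1e-12)
  # re-fitting at the winning node reproduces the winning SSR
  sp <- spec; sp$growth$T <- gs$best_T
  refit <- fit_tgi_continuous(x$data, sp,
                              fit_config(free = c("p0", "kin0", "wth"),
                                         start = as.list(gs$best_fit$estimates),
                                         n_starts = 1))
  expect_equal(refit$ssr, gs$best_fit$ssr,
               tolerance = 1e-10)
})

test_that("linear-only data identify the product pwth but not (p0, wth)", {
  des <- casestudy_template("az968", noise_cv = 0.02, seed = 9)
  st <- generate_study(des)
  ctl <- st$observations[st$observations$arm == "control", ]
  f1 <- fit_tgi_continuous(ctl, design_model_spec(des),
                           fit_config(free = c("pwth", "kin0"),
                                      n_starts = 1))
  expect_lt(f1$jtj_condition, 1e4)
  g2 <- growth_parameters("full", T = 1.28, kin0 = 49.9, w0 = 180,
                          p0 = 1.5, wth = 161.6)
  spec2 <- tgi_model_spec(g2, regimens = list(control = dose_regimen()))
  f2 <- fit_tgi_continuous(ctl, spec2,
                           fit_config(free = c("p0", "wth", "kin0"),
                                      n_starts = 1))
  expect_gt(f2$jtj_condition, 1e8)
})

test_that("control-only input produces a stage-1-only workflow report", {
  x <- pacli_control_data(noise_cv = 0.03, seed = 21)
  spec <- x$spec
  spec$hmax <- spec$growth$T / 30
  cfg <- fit_config(grid_T = c(1.40, 1.46, 1.52), refine = FALSE,
                    n_starts = 1, weighting = "proportional")
  wf <- fit_tgi_workflow(x$data, spec, cfg)
  expect_null(wf$stage2)
  expect_null(wf$stage3)
  expect_true(all(c("T", "p0", "kin0", "wth") %in% names(wf$estimates)))
  expect_s3_class(tidy(wf), "tbl_df")
})
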