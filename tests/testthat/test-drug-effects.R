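test_that("concentration-effect functions evaluate as specified", {
  lin <- drug_effect_spec("non_cycle_specific", "linear", TA = 1,
                          k2 = 2.30e-3)
  emx <- drug_effect_spec("cycle_specific", "emax", TA = 1, Emax = 0.8,
                          EC50 = 50)
  expect_equal(drug_effect(0, lin), 0)
  expect_equal(drug_effect(0, emx), 0)
  expect_equal(drug_effect(1000, lin), 2.30) # Table-4-like potency
  expect_equal(drug_effect(50, emx), 0.4)    # C = EC50 gives Emax/2
  C <- seq(0, 1e4, length.out = 100)
  expect_true(all(diff(drug_effect(C, lin)) >= 0))
  expect_true(all(diff(drug_effect(C, emx)) >= 0))
  expect_error(drug_effect(-1, lin), class = "lstgi_invalid")
  # cycle-specific removal is a fraction of dividing cells, so the
  # unbounded linear form is rejected at construction
  expect_error(drug_effect_spec("cycle_specific", "linear", TA = 1,
                                k2 = 1),
               class = "lstgi_invalid")
})

test_that("survival over one lifespan matches analytic and quadrature values", {
  # near-constant concentration C = 1: survival exp(-k2*T)
  pk <- pk_model(1, kel = 1e-9, V = 1, unit_scale = 1)
  prof <- simulate_concentration(pk, dose_regimen(0, 1, "iv"), 10)
  spec <- fig5_drug(TA = 1, k2 = 1.5)
  expect_equal(survival_fraction(prof, c(1, 2, 5), T = 1, spec),
               rep(exp(-1.5), 3), tolerance = 1e-6)
  # zero dose or zero potency: everything survives
  expect_equal(survival_fraction(drug_free_profile(10), c(0, 3, 7), 1,
                                 spec), rep(1, 3))
  expect_equal(survival_fraction(prof, c(2, 5), 1, fig5_drug(k2 = 0)),
               rep(1, 2))
  # emax form against adaptive quadrature on a dosed profile
  prof5 <- fig5_profile()
  em <- drug_effect_spec("non_cycle_specific", "emax", TA = 1, Emax = 0.8,
                         EC50 = 0.5)
  for (t in c(10.5, 11, 21)) {
    expo <- stats::integrate(function(s)
      drug_effect(concentration(prof5, s), em), t - 2, t,
      rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(survival_fraction(prof5, t, 2, em), exp(-expo),
                 tolerance = 1e-5)
  }
  expect_error(survival_fraction(prof5, 1, 1, fig6_drug()),
               class = "lstgi_invalid")
})

test_that("both perturbed simulators reduce to the unperturbed model without drug", {
  gp <- fig3_growth(w0 = 1)
  tt <- seq(0, 30, length.out = 200)
  ref <- simulate_tumor_growth(gp, 30, times = tt)
  prof0 <- drug_free_profile(30)
  ncs <- simulate_tgi(gp, fig5_drug(), prof0, 30, times = tt)
  expect_lt(max(abs(ncs$w - ref$w) / ref$w), 1e-6)
  expect_equal(max(ncs$A), 0)
  # dosed profile but zero potency / zero maximum effect
  prof5 <- fig5_profile(t_last = 30, times = c(10, 20))
  ncs0 <- simulate_tgi(gp, fig5_drug(k2 = 0), prof5, 30, times = tt)
  expect_lt(max(abs(ncs0$w - ref$w) / ref$w), 1e-6)
  cs0 <- simulate_tgi(gp, fig6_drug(Emax = 0), prof5, 30, times = tt)
  expect_lt(max(abs(cs0$w - ref$w) / ref$w), 1e-6)
  cs_weak <- simulate_tgi(gp, fig6_drug(Emax = 1, EC50 = 1e12), prof5, 30,
                          times = tt)
  expect_lt(max(abs(cs_weak$w - ref$w) / ref$w), 1e-6)
})

test_that("treatment never increases tumor size and potency orders trajectories", {
  gp <- fig3_growth(w0 = 1)
  tt <- seq(0, 45, length.out = 300)
  ctl <- simulate_tumor_growth(gp, 45, times = tt)
  prof <- fig5_profile()
  prev <- ctl$w
  for (k2 in c(0.2, 0.6, 1.5)) {
    cur <- simulate_tgi(gp, fig5_drug(k2 = k2), prof, 45, times = tt)$w
    expect_true(all(cur <= prev * (1 + 1e-5)))
    prev <- cur
  }
  # cycle-specific: increasing Emax is pointwise non-increasing during
  # treatment; a deeper nadir regrows marginally faster through the
  # size-dependent efficiency, so post-treatment curves may cross by a
  # fraction of a tenth of a percent
  prev <- ctl$w
  for (em in c(0.2, 0.6, 1)) {
    cur <- simulate_tgi(gp, fig6_drug(Emax = em, EC50 = 0.5), prof, 45,
                        times = tt)$w
    expect_true(all(cur <= prev * (1 + 1e-3)))
    expect_true(all((cur <= prev * (1 + 1e-6))[tt <= 34]))
    prev <- cur
  }
})

test_that("apoptotic pool bookkeeping matches its integral definition", {
  # constant inflow r from t = 0: A(t) = r * min(t, TA)
  tt <- seq(0, 10, by = 0.01)
  A <- apoptotic_pool(function(t) rep(2, length(t)), tt, TA = 3)
  expect_equal(A, 2 * pmin(tt, 3), tolerance = 1e-9)
  # zero inflow
  expect_equal(apoptotic_pool(function(t) rep(0, length(t)), tt, 3),
               rep(0, length(tt)))
  # a short triangular pulse (piecewise linear on the grid, so the
  # trapezoidal bookkeeping is exact) is held for TA and then released
  tt <- seq(0, 10, by = 0.002)
  pulse_v <- pmax(0, 1 - abs(tt - 1) / 0.05) * 5
  A <- apoptotic_pool(pulse_v, tt, TA = 4)
  expect_equal(max(A), 0.25, tolerance = 1e-9)
  held <- tt > 1.1 & tt < 4.9
  expect_equal(A[held], rep(0.25, sum(held)), tolerance = 1e-9)
  expect_equal(A[tt > 5.1], rep(0, sum(tt > 5.1)), tolerance = 1e-9)
  expect_error(apoptotic_pool(function(t) rep(-1, length(t)), tt, 4),
               class = "lstgi_invalid")
  expect_error(apoptotic_pool(function(t) rep(1, length(t)), tt, -1),
               class = "lstgi_invalid")
})

test_that("simulated apoptotic mass equals the lagged integral of the kill rate", {
  gp <- fig3_growth(w0 = 1)
  prof <- fig5_profile()
  spec <- fig5_drug()
  tt <- seq(0, 45, by = 0.001)
  tr <- simulate_tgi(gp, spec, prof, 45, times = tt)
  # jump-aware trapezoidal oracle: the kill rate E(C)*M jumps at bolus
  # times, so each interval is integrated with the right limit at its
  # start node and the left limit at its end node
  kill_right <- drug_effect(concentration(prof, tt), spec) * tr$M
  kill_left <- drug_effect(concentration(prof, tt - 1e-9), spec) * tr$M
  h <- diff(tt)
  cum <- c(0, cumsum(h * (head(kill_right, -1) + tail(kill_left, -1)) / 2))
  cum_at <- function(t) cum[match(round(t, 8), round(tt, 8))]
  probe <- c(12, 13.9, 14.5, 20.3, 24, 33.5, 41)
  A_or <- cum_at(probe) - cum_at(probe - spec$TA)
  A_sim <- tr$A[match(probe, tt)]
  expect_lt(max(abs(A_sim - A_or)) / max(tr$A), 1e-4)
  # cycle-specific: inflow is the partitioned division flux E * kin(t-T);
  # kin jumps every lifespan, so the dense trapezoidal oracle is
  # quadrature-limited and checked at a looser tolerance
  spec6 <- fig6_drug(EC50 = 0.5)
  tg <- seq(0, 45, by = 0.002)
  tr6 <- simulate_tgi(gp, spec6, prof, 45, times = tg)
  kin_lag <- c(rep(gp$kin0, sum(tg < gp$T)),
               tr6$kin[match(round(tg[tg >= gp$T] - gp$T, 8),
                             round(tg, 8))])
  inflow6 <- drug_effect(concentration(prof, tg), spec6) * kin_lag
  A6_oracle <- apoptotic_pool(inflow6, tg, spec6$TA)
  expect_lt(max(abs(tr6$A - A6_oracle)) / max(tr6$A), 5e-3)
})

test_that("raising TA delays the onset of decline without touching pre-dose growth", {
  gp <- fig3_growth(w0 = 1)
  prof <- fig5_profile()
  tt <- seq(0, 45, by = 0.01)
  onset <- function(w) tt[which(diff(w) < -1e-12)[1]]
  w4 <- simulate_tgi(gp, fig5_drug(TA = 4), prof, 45, times = tt)$w
  w6 <- simulate_tgi(gp, fig5_drug(TA = 6), prof, 45, times = tt)$w
  expect_equal(onset(w6) - onset(w4), 2, tolerance = 0.1)
  pre <- tt < 10
  expect_equal(w4[pre], w6[pre], tolerance = 1e-9)
})
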