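test_that("division efficiency has the stated shape and limits", {
  gp <- fig3_growth()
  # far below threshold the efficiency is p0
  expect_equal(division_efficiency(1e-3, gp), 2, tolerance = 1e-9)
  # decreasing towards 1 at infinity, for every form
  for (form in c("threshold_power", "switch_limit")) {
    w <- 10^seq(-2, 7, length.out = 120)
    p <- division_efficiency(w, gp, form = form)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 1 - 1e-12 & p <= 2 + 1e-12))
    expect_lt(p[length(p)] - 1, 1e-5)
  }
  gl <- growth_parameters("linear_phase", T = 1, kin0 = 0.05, w0 = 1,
                          pwth = (2 - 1) * 10)
  # above the threshold, the identifiable-product form equals the
  # infinite-sharpness switch limit
  w <- 10^seq(log10(10.01), 4, length.out = 50)
  expect_equal(division_efficiency(w, gl, form = "linear_phase"),
               division_efficiency(w, gp, form = "switch_limit"),
               tolerance = 1e-12)
  # finite sharpness converges to the switch away from the threshold
  gp200 <- growth_parameters("full", T = 1, kin0 = 0.05, w0 = 1, p0 = 2,
                             wth = 10, psi = 200)
  w <- c(10^seq(-2, log10(9.49), length.out = 40),
         10^seq(log10(10.51), 4, length.out = 40))
  expect_equal(division_efficiency(w, gp200),
               division_efficiency(w, gp200, form = "switch_limit"),
               tolerance = 0.01)
  expect_error(division_efficiency(-1, gp), class = "lstgi_invalid")
  expect_error(division_efficiency(0, gl, form = "linear_phase"),
               class = "lstgi_invalid")
})

test_that("constant-efficiency solution matches the discrete-sum closed form", {
  gp <- growth_parameters("constant_p", T = 1, kin0 = 0.05, w0 = 1, p0 = 2)
  expect_equal(closed_form_constant_p(gp, 0), 1)
  n <- 1:10
  expect_equal(closed_form_constant_p(gp, n * gp$T),
               gp$w0 + gp$kin0 * gp$T * (gp$p0^n - 1), tolerance = 1e-12)
  expect_equal(closed_form_constant_p(gp, 3), 1.35, tolerance = 1e-12)
  tg <- seq(0, 20, length.out = 501)
  tr <- simulate_tumor_growth(gp, 20, times = tg)
  expect_equal(tr$w, closed_form_constant_p(gp, tg), tolerance = 1e-9)
  expect_equal(simulate_tumor_growth(gp, 3, times = 3)$w, 1.35,
               tolerance = 1e-9)
})

test_that("exponential envelope bounds bracket the solution", {
  gp <- growth_parameters("constant_p", T = 1, kin0 = 0.05, w0 = 1, p0 = 2)
  tg <- seq(0, 20, length.out = 500)
  b <- asymptotic_bounds(gp, tg)
  wv <- closed_form_constant_p(gp, tg)
  expect_true(all(b$lower <= wv + 1e-9 * wv))
  expect_true(all(wv <= b$upper + 1e-9 * wv))
  expect_true(all(b$lower[1] <= gp$w0 & gp$w0 <= b$upper[1]))
  # ratio of the growing envelope terms never exceeds p0
  grow_lo <- b$lower - gp$w0 + gp$kin0 * gp$T
  grow_hi <- b$upper - gp$w0 + gp$kin0 * gp$T
  expect_true(all(grow_hi / grow_lo <= gp$p0 + 1e-9))
  expect_error(asymptotic_bounds(fig3_growth(), 1), class = "lstgi_invalid")
})

test_that("late linear phase has slope (p0-1)*wth/T, independent of kin0 and w0", {
  gp <- fig3_growth()
  expect_equal(linear_phase_slope(gp), (2 - 1) * 10 / 1)
  gp2 <- gp; gp2$wth <- 20
  expect_equal(linear_phase_slope(gp2), 2 * linear_phase_slope(gp))
  gp3 <- gp; gp3$T <- 2
  expect_equal(linear_phase_slope(gp3), linear_phase_slope(gp) / 2)
  measured_slope <- function(params) {
    tr <- simulate_tumor_growth(params, 40, times = seq(30, 40, 0.25))
    unname(coef(lm(w ~ time, data = tr))[2])
  }
  s0 <- measured_slope(gp)
  expect_equal(s0, linear_phase_slope(gp), tolerance = 0.05)
  # a 10x change in kin0 or a different w0 shifts growth in time only
  gp_k <- gp; gp_k$kin0 <- gp$kin0 * 10
  expect_equal(measured_slope(gp_k), s0, tolerance = 0.02)
  expect_equal(measured_slope(fig3_growth(w0 = 0.01)), s0,
               tolerance = 0.02)
  expect_error(linear_phase_slope(
    growth_parameters("constant_p", T = 1, kin0 = 1, w0 = 1, p0 = 2)),
    class = "lstgi_invalid")
})

test_that("growth is strictly monotone for p0 > 1 and static at p0 = 1", {
  set.seed(41)
  for (i in 1:5) {
    gp <- growth_parameters("full", T = runif(1, 0.5, 2),
                            kin0 = runif(1, 0.01, 0.2),
                            w0 = runif(1, 0.05, 2),
                            p0 = runif(1, 1.2, 2),
                            wth = runif(1, 2, 20))
    tr <- simulate_tumor_growth(gp, 10 * gp$T)
    expect_true(all(diff(tr$w) > 0))
    expect_equal(tr$w[1], gp$w0)
  }
  gp1 <- growth_parameters("constant_p", T = 1, kin0 = 0.05, w0 = 1,
                           p0 = 1)
  tr <- simulate_tumor_growth(gp1, 10)
  expect_equal(tr$w, rep(1, nrow(tr)), tolerance = 1e-12)
})

test_that("tumor size doubles every lifespan under full constant efficiency", {
  gp <- growth_parameters("constant_p", T = 1.3, kin0 = 0.05, w0 = 0.5,
                          p0 = 2)
  t0 <- seq(10, 20, by = 0.5) * gp$T
  tr0 <- simulate_tumor_growth(gp, 21 * gp$T, times = t0)
  tr1 <- simulate_tumor_growth(gp, 21 * gp$T, times = t0 + gp$T)
  expect_equal(tr1$w / tr0$w, rep(2, length(t0)), tolerance = 0.01)
})

test_that("method of steps agrees with a brute-force fixed-step oracle", {
  set.seed(7)
  for (i in 1:10) {
    gp <- growth_parameters("full", T = runif(1, 0.5, 2),
                            kin0 = runif(1, 0.01, 0.1),
                            w0 = runif(1, 0.01, 1),
                            p0 = runif(1, 1.3, 2),
                            wth = runif(1, 2, 20))
    t_last <- 20 * gp$T
    oracle <- brute_unperturbed(gp, t_last, n_per_T = 2000)
    keep <- seq(1, length(oracle$time), by = 400)
    tr <- simulate_tumor_growth(gp, t_last, times = oracle$time[keep])
    expect_lt(max(abs(tr$w - oracle$w[keep]) / oracle$w[keep]), 1e-5)
  }
})
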