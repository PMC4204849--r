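test_that("one-compartment oral profile with kel = ka matches the analytic limit", {
  pk <- pk_model(1, kel = 5.52, ka = 5.52, V = 4.86)
  D <- 10
  prof <- simulate_concentration(pk, dose_regimen(0, D, "po"), 5)
  tt <- seq(0.05, 4, length.out = 20)
  expect_equal(concentration(prof, tt),
               (D / 4.86) * 5.52 * tt * exp(-5.52 * tt) * 1000,
               tolerance = 1e-12)
  # cumulative evaluator agrees with quadrature of the point evaluator
  for (t1 in c(0.5, 2, 4)) {
    q <- stats::integrate(function(s) concentration(prof, s), 0, t1,
                          rel.tol = 1e-10)$value
    expect_equal(cumulative_exposure(prof, 0, t1), q, tolerance = 1e-7)
  }
})

test_that("linear kinetics superpose and scale with dose", {
  pk <- pk_model(2, kel = 24.7, k12 = 8.74, k21 = 11.2, V = 1.97,
                 ka = 46.8)
  multi <- simulate_concentration(
    pk, dose_regimen(c(0, 7, 14), 20, "ip"), 25)
  singles <- lapply(c(0, 7, 14), function(td) {
    simulate_concentration(pk, dose_regimen(td, 20, "ip"), 25)
  })
  tt <- seq(0, 25, length.out = 300)
  sum_c <- Reduce(`+`, lapply(singles, concentration, t = tt))
  expect_equal(concentration(multi, tt), sum_c, tolerance = 1e-12)

  doubled <- simulate_concentration(
    pk, dose_regimen(c(0, 7, 14), 40, "ip"), 25)
  expect_equal(concentration(doubled, tt), 2 * concentration(multi, tt),
               tolerance = 1e-12)
})

test_that("closed-form bolus profile agrees with an ODE oracle", {
  kel <- 0.868 * 24; k12 <- 0.006 * 24; k21 <- 0.0838 * 24; V <- 0.81
  pk <- pk_model(2, kel = kel, k12 = k12, k21 = k21, V = V)
  prof <- simulate_concentration(pk, dose_regimen(0, 30, "iv"), 2)
  rhs <- function(t, y, p) {
    list(c(-(kel + k12) * y[1] + k21 * y[2], k12 * y[1] - k21 * y[2]))
  }
  tt <- seq(0, 2, length.out = 200)
  ode <- deSolve::lsoda(c(30 / V * 1000, 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-8)
  expect_equal(concentration(prof, tt), ode[, 2],
               tolerance = 1e-6)
})

test_that("empty regimens and empty intervals give zero drug", {
  prof <- drug_free_profile(30)
  tt <- seq(0, 30, length.out = 50)
  expect_equal(concentration(prof, tt), rep(0, 50))
  expect_identical(cumulative_exposure(prof, 0, 30), 0)
  dosed <- fig5_profile()
  expect_equal(cumulative_exposure(dosed, 12, 12), 0)
  # pre-dose times contribute nothing
  expect_equal(concentration(dosed, c(0, 5, 9.99)), rep(0, 3))
  # negative t0 is clipped at zero
  expect_equal(cumulative_exposure(dosed, -5, 15),
               cumulative_exposure(dosed, 0, 15))
})

test_that("dose-level PK overrides select per-dose constants", {
  pk <- pk_model(2, kel = 24.7, k12 = 8.74, k21 = 11.2, V = 1.97,
                 ka = 46.8,
                 per_dose = list("10" = list(kel = 33.9, V = 2.70),
                                 "30" = list(kel = 24.7, V = 1.97)))
  p10 <- simulate_concentration(pk, dose_regimen(0, 10, "ip"), 3)
  p30 <- simulate_concentration(pk, dose_regimen(0, 30, "ip"), 3)
  # 10 mg/kg with its larger V and faster kel is less than one third of
  # the 30 mg/kg curve
  tt <- seq(0.05, 1, length.out = 30)
  expect_true(all(concentration(p10, tt) < concentration(p30, tt) / 3 +
                    1e-9))
  expect_error(simulate_concentration(pk, dose_regimen(0, 20, "ip"), 3),
               class = "lstgi_pk_error")
})

test_that("invalid PK inputs are rejected", {
  expect_error(pk_model(1, kel = 1, V = 1, k12 = 0.1),
               class = "lstgi_invalid")
  expect_error(pk_model(3, kel = 1, V = 1), class = "lstgi_invalid")
  pk <- pk_model(1, kel = 1, V = 1) # no ka
  expect_error(simulate_concentration(pk, dose_regimen(0, 5, "po"), 2),
               class = "lstgi_pk_error")
  expect_error(simulate_concentration(pk, dose_regimen(c(0, 4), 5, "iv"),
                                      3),
               class = "lstgi_invalid") # t_last before last dose
  expect_error(dose_regimen(c(1, 1), 5, "iv"), class = "lstgi_invalid")
  prof <- drug_free_profile(10)
  expect_error(cumulative_exposure(prof, 5, 2), class = "lstgi_invalid")
})
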