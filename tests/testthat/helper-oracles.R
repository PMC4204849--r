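# Independent oracles and shared fixtures.  The brute-force integrator is a
# deliberately simple midpoint (RK2) scheme on a uniform grid with the
# production rate stored pointwise -- it shares no code with the package's
# method-of-steps solver.

# unperturbed lifespan DDE: dw/dt = (p(w)-1)*kin(t-T), kin(t)=p(w)*kin(t-T)
brute_unperturbed <- function(params, t_last, n_per_T = 2000,
                              form = c("threshold_power", "constant",
                                       "switch_limit", "linear_phase")) {
  form <- match.arg(form)
  T <- params$T
  h <- T / n_per_T
  n_steps <- ceiling(t_last / h)
  p0 <- params$p0; wth <- params$wth; psi <- params$psi
  p_of <- switch(form,
    constant = function(w) p0,
    threshold_power = function(w) {
      r <- w / wth
      u <- if (r <= 1) (1 + r^psi)^(-1 / psi)
           else (1 / r) * (1 + r^(-psi))^(-1 / psi)
      1 + (p0 - 1) * u
    },
    switch_limit = function(w) if (w <= wth) p0 else 1 + (p0 - 1) * wth / w,
    linear_phase = function(w) 1 + params$pwth / w)
  t <- (0:n_steps) * h
  nlag <- n_per_T # exact: T/h
  w <- numeric(n_steps + 1)
  w[1] <- params$w0
  # R[j+1] = k_in at grid point j taken from the piece to its RIGHT
  # (the recursion applied at t_j); the history value kin0 applies left
  # of 0.  At generation boundaries (multiples of T) k_in jumps, and the
  # value a step uses depends on which side of the boundary its lag
  # interval lies: the step STARTING at a boundary uses the right piece,
  # the step ENDING there the left piece.
  R <- numeric(n_steps + 1)
  R[1] <- p_of(w[1]) * params$kin0
  Lv <- params$kin0 # Lv[m+1] = left limit of k_in at the boundary m*T
  lag_right <- function(j) if (j < 0) params$kin0 else R[j + 1]
  for (i in 0:(n_steps - 1)) {
    j <- i - nlag
    k_start <- lag_right(j)
    k_end <- if (j + 1 < 0) {
      params$kin0
    } else if ((j + 1) %% nlag == 0) {
      Lv[(j + 1) %/% nlag + 1] # left limit at the lag boundary
    } else {
      lag_right(j + 1)
    }
    k_half <- (k_start + k_end) / 2
    w_half <- w[i + 1] + (h / 2) * (p_of(w[i + 1]) - 1) * k_start
    w[i + 2] <- w[i + 1] + h * (p_of(w_half) - 1) * k_half
    R[i + 2] <- p_of(w[i + 2]) * lag_right(j + 1)
    if ((i + 1) %% nlag == 0) {
      m_new <- (i + 1) %/% nlag
      # left limit at m_new*T: recursion through the previous left limit
      Lv[m_new + 1] <- p_of(w[i + 2]) * Lv[m_new]
    }
  }
  list(time = t, w = w)
}

# trapezoidal running integral on a dense grid
trapz_cum <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

fig3_growth <- function(w0 = 0.001) {
  growth_parameters("full", T = 1, kin0 = 0.05, w0 = w0, p0 = 2, wth = 10)
}

# dimensionless sensitivity-analysis PK: 2-compartment bolus, V = 1 mL,
# doses of 10 units at days 10, 20, 30
fig5_profile <- function(t_last = 45, amounts = 10,
                         times = c(10, 20, 30)) {
  pk <- pk_model(2, kel = 20, k12 = 0.2, k21 = 2, V = 1, unit_scale = 1)
  simulate_concentration(pk, dose_regimen(times, amounts, "iv"), t_last)
}

fig5_drug <- function(TA = 4, k2 = 1.5) {
  drug_effect_spec("non_cycle_specific", "linear", TA = TA, k2 = k2)
}

fig6_drug <- function(TA = 4, Emax = 1, EC50 = 0.01) {
  drug_effect_spec("cycle_specific", "emax", TA = TA, Emax = Emax,
                   EC50 = EC50)
}

paclitaxel_pk <- function() {
  pk_model(2, kel = 0.868 * 24, k12 = 0.006 * 24, k21 = 0.0838 * 24,
           V = 0.81)
}

drug_free_profile <- function(t_last) {
  simulate_concentration(pk_model(1, kel = 1, V = 1), dose_regimen(),
                         t_last)
}
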