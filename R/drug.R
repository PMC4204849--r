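#' Anticancer drug effect specification
#'
#' Two mechanisms are supported.  A *non-cycle-specific* drug removes
#' proliferating cells continuously, at any point of their lifespan, at
#' rate \eqn{E(C(t)) M(t)}; only cells that survive the exposure integral
#' over their lifespan divide, so the lagged production term carries the
#' survival factor \eqn{\exp(-\int_{t-T}^t E(C(s)) ds)}.  A
#' *cycle-specific* drug acts only at the moment of division: a fraction
#' \eqn{E(C(t))} of cells reaching the end of their lifespan is diverted to
#' the apoptotic pool instead of dividing, which requires the bounded Emax
#' effect form.  In both cases affected cells join a non-proliferating pool
#' `A` that leaves the tumor mass after an apoptosis lifespan `TA`.
#'
#' @param mechanism `"non_cycle_specific"` or `"cycle_specific"`.
#' @param effect_form `"linear"` (\eqn{E = k_2 C}, a per-day rate) or
#'   `"emax"` (\eqn{E = E_{max} C / (EC_{50} + C)}, a fraction).  The
#'   cycle-specific mechanism requires `"emax"`.
#' @param TA Apoptosis duration (day, > 0).
#' @param k2 Second-order potency constant, mL/ng/day (linear form).
#' @param Emax Maximum effect, in \[0, 1\] (emax form).
#' @param EC50 Concentration of half-maximal effect, ng/mL (emax form).
#' @return An object of class `drug_effect_spec`.
#' @examples
#' drug_effect_spec("non_cycle_specific", "linear", TA = 5.56, k2 = 2.3e-3)
#' drug_effect_spec("cycle_specific", "emax", TA = 0.536, Emax = 1,
#'                  EC50 = 9.45)
#' @export
drug_effect_spec <- function(mechanism = c("non_cycle_specific",
                                           "cycle_specific"),
                             effect_form = c("linear", "emax"), TA,
                             k2 = NULL, Emax = NULL, EC50 = NULL) {
  mechanism <- match.arg(mechanism)
  effect_form <- match.arg(effect_form)
  check_number(TA, "TA", lower = .Machine$double.eps)
  if (mechanism == "cycle_specific" && effect_form != "emax") {
    ls_abort(paste("the cycle-specific mechanism partitions dividing cells",
                   "and needs the bounded emax effect form"),
             "lstgi_invalid")
  }
  if (effect_form == "linear") {
    check_number(k2, "k2", lower = 0)
  } else {
    check_number(Emax, "Emax", lower = 0, upper = 1)
    check_number(EC50, "EC50", lower = .Machine$double.eps)
  }
  structure(
    list(mechanism = mechanism, effect_form = effect_form, k2 = k2,
         Emax = Emax, EC50 = EC50, TA = TA),
    class = "drug_effect_spec"
  )
}

#' Concentration-effect function
#'
#' @param C Plasma concentrations, ng/mL (`>= 0`).
#' @param spec A [drug_effect_spec()].
#' @return `k2 * C` (per day) for the linear form, or
#'   `Emax * C / (EC50 + C)` (dimensionless) for the emax form.
#' @export
drug_effect <- function(C, spec) {
  stopifnot(inherits(spec, "drug_effect_spec"))
  if (any(!is.finite(C)) || any(C < 0)) {
    ls_abort("`C` must be finite and non-negative", "lstgi_invalid")
  }
  if (spec$effect_form == "linear") spec$k2 * C
  else spec$Emax * C / (spec$EC50 + C)
}

#' Fraction of cells surviving drug exposure over one lifespan
#'
#' For the non-cycle-specific mechanism, the fraction of cells born at
#' `t - T` that survive to divide at `t` is
#' \eqn{\exp(-\int_{\max(t-T,\,0)}^{t} E(C(s))\, ds)}; exposure before time
#' 0 contributes nothing.  The exposure integral uses the profile's exact
#' antiderivative for the linear effect form and adaptive quadrature for
#' the emax form.
#'
#' @param profile A [simulate_concentration()] result.
#' @param t Evaluation times, day (vectorized, `>= 0`).
#' @param T Cell lifespan, day.
#' @param spec A [drug_effect_spec()] with the non-cycle-specific
#'   mechanism.
#' @return Survival fractions in `(0, 1]`.
#' @export
survival_fraction <- function(profile, t, T, spec) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(spec, "drug_effect_spec"))
  if (spec$mechanism != "non_cycle_specific") {
    ls_abort("survival over a lifespan is defined for the non-cycle-specific
              mechanism only", "lstgi_invalid")
  }
  if (any(t < 0)) ls_abort("`t` must be >= 0", "lstgi_invalid")
  vapply(t, function(tt) {
    lo <- max(tt - T, 0)
    expo <- if (spec$effect_form == "linear") {
      spec$k2 * cumulative_exposure(profile, lo, tt)
    } else {
      if (lo >= tt || nrow(profile$terms) == 0) 0
      else stats::integrate(function(s)
        drug_effect(concentration(profile, s), spec), lo, tt,
        rel.tol = 1e-9, subdivisions = 400L)$value
    }
    exp(-expo)
  }, numeric(1))
}

#' Simulate drug-perturbed tumor growth
#'
#' Integrates the perturbed lifespan model for either drug mechanism by
#' the method of steps, with restarts at dose times and at the lag lattice
#' generated by `T` and `TA`.  The proliferating mass `M` starts at `w0`,
#' the apoptotic pool `A` at 0, and the division efficiency is evaluated at
#' the total size `w = M + A` (the proliferation burden includes dying
#' cells still physically present in the tumor) unless `p_of_total` is
#' `FALSE`.
#'
#' @param growth A [growth_parameters()] object.
#' @param drug A [drug_effect_spec()].
#' @param profile A [simulate_concentration()] result covering
#'   `[0, t_last]`.
#' @param t_last Simulation horizon, day.
#' @param times Output times (default 400-point grid).
#' @param form Efficiency form override.
#' @param hmax Maximum integrator step (default `min(T/80, TA/8)`).
#' @param p_of_total Evaluate `p` at `M + A` (default) or at `M` only
#'   (sensitivity switch).
#' @return A tibble of class `tgi_trajectory` with columns `time`, `M`,
#'   `A`, `w = M + A`, and `kin`.
#' @export
simulate_tgi <- function(growth, drug, profile, t_last, times = NULL,
                         form = NULL, hmax = NULL, p_of_total = TRUE) {
  stopifnot(inherits(growth, "growth_parameters"),
            inherits(drug, "drug_effect_spec"),
            inherits(profile, "concentration_profile"))
  check_number(t_last, "t_last", lower = .Machine$double.eps)
  if (t_last > profile$t_last + 1e-9) {
    ls_abort("the concentration profile does not cover [0, t_last]",
             "lstgi_invalid")
  }
  form <- form %||% default_form(growth)
  times <- times %||% seq(0, t_last, length.out = 400)
  if (any(times < 0) || any(times > t_last + 1e-9)) {
    ls_abort("`times` must lie within [0, t_last]", "lstgi_invalid")
  }
  hmax <- hmax %||% default_hmax(growth, drug)
  mech <- if (drug$mechanism == "non_cycle_specific") 1L else 2L
  ca <- core_args_growth(growth, form)
  res <- ls_core_simulate(
    times_out = as.numeric(times), t_last = t_last, T = growth$T,
    kin0 = growth$kin0, w0 = growth$w0, eff_form = ca$eff_form, p0 = ca$p0,
    wth = ca$wth, psi = ca$psi, pwth = ca$pwth, mechanism = mech,
    effect_form = if (drug$effect_form == "linear") 0L else 1L,
    k2 = drug$k2 %||% 0, Emax = drug$Emax %||% 0, EC50 = drug$EC50 %||% 1,
    TA = drug$TA, pk_terms = profile$terms,
    dose_times = profile$dose_times, hmax = hmax, p_of_total = p_of_total)
  out <- tibble(time = res$time, M = res$M, A = res$A, w = res$w,
                kin = res$kin)
  structure(out, class = c("tgi_trajectory", class(out)), growth = growth,
            drug = drug, form = form, t_last = t_last)
}

#' Apoptotic pool from a removal-rate signal
#'
#' The non-proliferating pool holds every cell for exactly `TA` days, so
#' \eqn{A(t) = \int_{\max(t - T_A,\, 0)}^{t} \mathrm{inflow}(s)\, ds} with
#' `A(0) = 0`.  Used as an independent bookkeeping check on the simulators.
#'
#' @param inflow A function of time or a numeric vector on `times` giving
#'   the removal rate (mass/day, `>= 0`).
#' @param times Evaluation grid (day, sorted, starting at 0).
#' @param TA Apoptosis duration, day (> 0).
#' @param n_sub Subdivisions per output interval for the internal
#'   trapezoidal accumulation when `inflow` is a function.
#' @return A numeric vector `A(times)`.
#' @export
apoptotic_pool <- function(inflow, times, TA, n_sub = 20L) {
  check_number(TA, "TA", lower = .Machine$double.eps)
  if (is.function(inflow)) {
    dense <- unique(sort(c(
      seq(min(times), max(times), length.out = n_sub * length(times)),
      times)))
    vals <- inflow(dense)
  } else {
    dense <- times
    vals <- inflow
  }
  if (any(vals < -1e-12)) {
    ls_abort("removal inflow must be non-negative", "lstgi_invalid")
  }
  cum <- c(0, cumsum(diff(dense) * (head(vals, -1) + tail(vals, -1)) / 2))
  cum_at <- function(q) {
    q <- pmin(pmax(q, dense[1]), dense[length(dense)])
    approx(dense, cum, xout = q, rule = 2)$y
  }
  cum_at(times) - cum_at(pmax(times - TA, min(times)))
}

#' @export
autoplot.tgi_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[c("time", "M", "A", "w")],
                              -"time", names_to = "compartment",
                              values_to = "mass")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mass,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (day)", y = "Mass",
                  colour = NULL)
}
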