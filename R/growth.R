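#' Parameters of the unperturbed lifespan tumor growth model
#'
#' The tumor is a population of cells that each live exactly `T` days and
#' divide at the end of their lifespan into `p(w)` effective daughter
#' cells, where the division efficiency `p` lies between 1 (stasis) and 2
#' (full doubling) and decreases with total tumor size `w`.  Elimination is
#' the production rate lagged by one lifespan, giving the delay equation
#' \deqn{dw/dt = (p(w(t)) - 1)\, k_{in}(t - T), \qquad
#'       k_{in}(t) = p(w(t))\, k_{in}(t - T),}
#' with constant pre-experiment history \eqn{k_{in}(t) = k_{in0}} on
#' \eqn{(-T, 0]} and \eqn{w(0) = w_0}.
#'
#' Three parameterizations are supported:
#' * `"full"` — size-dependent efficiency with threshold `wth` and switch
#'   sharpness `psi` (biphasic exponential-then-linear growth);
#' * `"linear_phase"` — all observations beyond the threshold, where only
#'   the product `pwth = (p0 - 1) * wth` is identifiable;
#' * `"constant_p"` — constant efficiency `p0` (pure exponential growth,
#'   admits a closed-form solution).
#'
#' @param mode One of `"full"`, `"linear_phase"`, `"constant_p"`.
#' @param T Cell lifespan / tumor doubling time, day.
#' @param kin0 Pre-experiment production rate, mass/day.
#' @param w0 Tumor size at time 0 (mass; grams or mm^3, whichever unit the
#'   observations use -- the model never converts between them).
#' @param p0 Division efficiency below the threshold, in \[1, 2\].
#' @param wth Threshold tumor size (mass) above which efficiency falls off.
#'   Setting a sentinel far above the observed sizes makes growth purely
#'   exponential.
#' @param psi Switch sharpness of the efficiency function (dimensionless,
#'   default 20, normally kept fixed).
#' @param pwth Identifiable product `(p0 - 1) * wth` (mass), used only in
#'   `linear_phase` mode.
#' @return An object of class `growth_parameters`.
#' @examples
#' growth_parameters("full", T = 1, kin0 = 0.05, w0 = 0.001, p0 = 2,
#'                   wth = 10)
#' @export
growth_parameters <- function(mode = c("full", "linear_phase", "constant_p"),
                              T, kin0, w0, p0 = NULL, wth = NULL, psi = 20,
                              pwth = NULL) {
  mode <- match.arg(mode)
  check_number(T, "T", lower = .Machine$double.eps)
  check_number(kin0, "kin0", lower = 0)
  check_number(w0, "w0", lower = .Machine$double.eps)
  check_number(psi, "psi", lower = .Machine$double.eps)
  if (mode == "linear_phase") {
    check_number(pwth, "pwth", lower = .Machine$double.eps)
  } else {
    check_number(p0, "p0", lower = 1, upper = 2)
    if (mode == "full") check_number(wth, "wth", lower = .Machine$double.eps)
  }
  structure(
    list(mode = mode, T = T, kin0 = kin0, w0 = w0, p0 = p0, wth = wth,
         psi = psi, pwth = pwth),
    class = "growth_parameters"
  )
}

eff_form_code <- function(form) {
  switch(form, constant = 0L, threshold_power = 1L, switch_limit = 2L,
         linear_phase = 3L,
         ls_abort(sprintf("unknown efficiency form '%s'", form),
                  "lstgi_invalid"))
}

default_form <- function(params) {
  switch(params$mode, full = "threshold_power",
         linear_phase = "linear_phase", constant_p = "constant")
}

#' Cell division efficiency as a function of tumor size
#'
#' Available forms:
#' * `"threshold_power"`:
#'   \eqn{p(w) = 1 + (p_0-1)\,(1 + (w/w_{th})^\psi)^{-1/\psi}} -- smooth
#'   switch from `p0` below the threshold towards 1 as `w` grows;
#' * `"switch_limit"`: the \eqn{\psi \to \infty} limit, `p0` for
#'   `w <= wth` and \eqn{1 + (p_0-1) w_{th} / w} above;
#' * `"linear_phase"`: \eqn{1 + p_{wth}/w}, valid once observations exceed
#'   the threshold;
#' * `"constant"`: \eqn{p \equiv p_0}.
#'
#' @param w Tumor sizes (mass), `>= 0` (`> 0` for the `linear_phase` form).
#' @param params A [growth_parameters()] object.
#' @param form Efficiency form; defaults to the form implied by
#'   `params$mode`.
#' @return Efficiencies in `[1, p0]`, non-increasing in `w`.
#' @export
division_efficiency <- function(w, params, form = NULL) {
  stopifnot(inherits(params, "growth_parameters"))
  form <- form %||% default_form(params)
  code <- eff_form_code(form)
  if (any(!is.finite(w)) || any(w < 0)) {
    ls_abort("`w` must be finite and non-negative", "lstgi_invalid")
  }
  if (code == 3L && any(w == 0)) {
    ls_abort("the linear-phase efficiency form is undefined at w = 0",
             "lstgi_invalid")
  }
  p0 <- params$p0 %||% NA_real_
  wth <- params$wth %||% NA_real_
  psi <- params$psi
  pwth <- params$pwth %||% NA_real_
  vapply(w, function(wi) {
    switch(as.character(code),
      "0" = p0,
      "1" = {
        r <- wi / wth
        u <- if (r <= 0) 1
             else if (r <= 1) (1 + r^psi)^(-1 / psi)
             else (1 / r) * (1 + r^(-psi))^(-1 / psi)
        1 + (p0 - 1) * u
      },
      "2" = if (wi <= wth) p0 else 1 + (p0 - 1) * wth / wi,
      "3" = 1 + pwth / wi
    )
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_pk_terms <- function() {
  matrix(numeric(0), ncol = 4,
         dimnames = list(NULL, c("t_dose", "coef", "rate", "type")))
}

default_hmax <- function(params, drug = NULL) {
  h <- params$T / 80
  if (!is.null(drug)) h <- min(h, drug$TA / 8)
  h
}

core_args_growth <- function(params, form) {
  list(eff_form = eff_form_code(form),
       p0 = params$p0 %||% 0,
       wth = params$wth %||% 1,
       psi = params$psi,
       pwth = params$pwth %||% 0)
}

#' Simulate unperturbed tumor growth
#'
#' Solves the lifespan growth delay differential equation by the method of
#' steps: on each interval between consecutive multiples of `T` the lagged
#' production rate is known from stored dense history, and integration
#' restarts at each multiple because the recursion depth of
#' \eqn{k_{in}} jumps there.
#'
#' @param params A [growth_parameters()] object.
#' @param t_last Simulation horizon, day (> 0).
#' @param times Output times (default: a 400-point grid over
#'   `[0, t_last]`).
#' @param form Efficiency form override (see [division_efficiency()]).
#' @param hmax Maximum integrator step, day (default `T/80`).
#' @return A tibble of class `tumor_trajectory` with columns `time`, `w`,
#'   and `kin` (the production-rate signal), carrying the parameters as
#'   attributes.
#' @examples
#' gp <- growth_parameters("constant_p", T = 1, kin0 = 0.05, w0 = 1, p0 = 2)
#' simulate_tumor_growth(gp, t_last = 3, times = 0:3)
#' @export
simulate_tumor_growth <- function(params, t_last, times = NULL, form = NULL,
                                  hmax = NULL) {
  stopifnot(inherits(params, "growth_parameters"))
  check_number(t_last, "t_last", lower = .Machine$double.eps)
  form <- form %||% default_form(params)
  times <- times %||% seq(0, t_last, length.out = 400)
  if (any(times < 0) || any(times > t_last + 1e-9)) {
    ls_abort("`times` must lie within [0, t_last]", "lstgi_invalid")
  }
  hmax <- hmax %||% default_hmax(params)
  ca <- core_args_growth(params, form)
  res <- ls_core_simulate(
    times_out = as.numeric(times), t_last = t_last, T = params$T,
    kin0 = params$kin0, w0 = params$w0, eff_form = ca$eff_form, p0 = ca$p0,
    wth = ca$wth, psi = ca$psi, pwth = ca$pwth, mechanism = 0L,
    effect_form = 0L, k2 = 0, Emax = 0, EC50 = 1, TA = 1,
    pk_terms = empty_pk_terms(), dose_times = numeric(), hmax = hmax,
    p_of_total = TRUE)
  out <- tibble(time = res$time, w = res$w, kin = res$kin)
  structure(out, class = c("tumor_trajectory", class(out)),
            params = params, form = form, t_last = t_last)
}

#' Closed-form solution under constant division efficiency
#'
#' With \eqn{p \equiv p_0} the production rate is piecewise constant,
#' \eqn{k_{in} = k_{in0} p_0^{n+1}} on \eqn{(nT, (n+1)T]}, and the tumor
#' size is the explicit piecewise-linear-in-t expression
#' \deqn{w(t) = w_0 + k_{in0} T (p_0^{n} - 1) +
#'       (p_0 - 1) k_{in0} p_0^{n} (t - nT), \quad n = INT(t/T).}
#'
#' @param params [growth_parameters()] with `mode = "constant_p"`.
#' @param t Times, day (vectorized, `>= 0`).
#' @return Tumor sizes (mass).
#' @export
closed_form_constant_p <- function(params, t) {
  stopifnot(inherits(params, "growth_parameters"))
  if (params$mode != "constant_p") {
    ls_abort("closed form requires mode = 'constant_p'", "lstgi_invalid")
  }
  if (any(t < 0)) ls_abort("`t` must be >= 0", "lstgi_invalid")
  p0 <- params$p0
  T <- params$T
  n <- floor(t / T + 1e-12)
  params$w0 + params$kin0 * T * (p0^n - 1) +
    (p0 - 1) * params$kin0 * p0^n * (t - n * T)
}

#' Exponential envelope bounds for constant-efficiency growth
#'
#' Because \eqn{0 \le t/T - INT(t/T) < 1}, the piecewise solution is
#' bracketed by smooth exponentials in \eqn{p_0^{t/T}}:
#' \deqn{w_0 + k_{in0} T (p_0^{t/T} - 1) \le w(t) \le
#'       w_0 + k_{in0} T (p_0^{t/T + 1} - 1),}
#' so the tumor grows exponentially as \eqn{p_0^{t/T}} and the ratio of the
#' two growing envelope terms never exceeds \eqn{p_0}.
#'
#' @inheritParams closed_form_constant_p
#' @return A tibble with columns `time`, `lower`, `upper`.
#' @export
asymptotic_bounds <- function(params, t) {
  stopifnot(inherits(params, "growth_parameters"))
  if (params$mode != "constant_p") {
    ls_abort("bounds require mode = 'constant_p'", "lstgi_invalid")
  }
  if (any(t < 0)) ls_abort("`t` must be >= 0", "lstgi_invalid")
  p0 <- params$p0
  g <- p0^(t / params$T)
  tibble(time = t,
         lower = params$w0 + params$kin0 * params$T * (g - 1),
         upper = params$w0 + params$kin0 * params$T * (p0 * g - 1))
}

#' Slope of the late linear growth phase
#'
#' Once the tumor exceeds the threshold the efficiency approaches
#' \eqn{1 + (p_0-1) w_{th}/w} and, for lifespans short relative to the
#' horizon, the size grows linearly with slope
#' \deqn{\mathrm{slope} = (p_0 - 1)\, w_{th} / T = p_{wth} / T,}
#' independent of `kin0` and `w0`.
#'
#' @param params [growth_parameters()] in `full` or `linear_phase` mode.
#' @return Slope in mass/day.
#' @export
linear_phase_slope <- function(params) {
  stopifnot(inherits(params, "growth_parameters"))
  if (params$mode == "constant_p") {
    ls_abort("constant-efficiency growth has no linear phase",
             "lstgi_invalid")
  }
  pwth <- if (params$mode == "linear_phase") params$pwth
          else (params$p0 - 1) * params$wth
  pwth / params$T
}

#' @export
autoplot.tumor_trajectory <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$w)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (day)", y = "Tumor size")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
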