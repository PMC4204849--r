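#' Compartmental pharmacokinetic model specification
#'
#' Defines a one- or two-compartment disposition model with optional
#' first-order absorption, used to drive plasma concentration \eqn{C(t)} in
#' the tumor growth inhibition simulators.  All rate constants are in 1/day
#' and the apparent central volume `V` in L/kg (interpreted as `V/F` for
#' oral dosing), so a dose in mg/kg divided by `V` gives \eqn{\mu}g/mL,
#' converted to ng/mL with `unit_scale = 1000`.
#'
#' Nonlinear (dose-level-specific) kinetics are expressed through
#' `per_dose`, a named list keyed by dose amount whose elements are lists
#' with `kel` and/or `V` overriding the common values; each dose event then
#' evolves with its own linear constants and profiles superpose.
#'
#' @param n_compartments 1 or 2.
#' @param kel Elimination rate constant (1/day).
#' @param V Apparent central volume (L/kg).
#' @param ka First-order absorption rate constant (1/day); required for
#'   `ip`/`po` dose routes, ignored for `iv`.
#' @param k12,k21 Inter-compartment rate constants (1/day); must be 0 for a
#'   one-compartment model.
#' @param per_dose Optional named list of per-dose-level overrides, e.g.
#'   `list("10" = list(kel = 33.9, V = 2.70))`.
#' @param unit_scale Multiplier taking dose/V to the concentration unit of
#'   the effect model (default 1000: mg/kg over L/kg to ng/mL).  Set to 1
#'   for dimensionless simulation fixtures.
#' @return An object of class `pk_model`.
#' @examples
#' # paclitaxel disposition (rates published per hour, converted to 1/day)
#' pk_model(2, kel = 0.868 * 24, k12 = 0.006 * 24, k21 = 0.0838 * 24,
#'          V = 0.81)
#' @export
pk_model <- function(n_compartments, kel, V, ka = NULL, k12 = 0, k21 = 0,
                     per_dose = NULL, unit_scale = 1000) {
  if (!n_compartments %in% c(1, 2)) {
    ls_abort("`n_compartments` must be 1 or 2", "lstgi_invalid")
  }
  check_number(kel, "kel", lower = 0)
  check_number(V, "V", lower = .Machine$double.eps)
  check_number(k12, "k12", lower = 0)
  check_number(k21, "k21", lower = 0)
  check_number(unit_scale, "unit_scale", lower = .Machine$double.eps)
  if (!is.null(ka)) check_number(ka, "ka", lower = 0)
  if (n_compartments == 1 && (k12 > 0 || k21 > 0)) {
    ls_abort("one-compartment model requires k12 = k21 = 0", "lstgi_invalid")
  }
  if (!is.null(per_dose)) {
    if (is.null(names(per_dose)) || any(names(per_dose) == "")) {
      ls_abort("`per_dose` must be a named list keyed by dose amount",
               "lstgi_invalid")
    }
    bad <- vapply(per_dose, function(el) {
      !is.list(el) || !all(names(el) %in% c("kel", "V"))
    }, logical(1))
    if (any(bad)) {
      ls_abort("`per_dose` elements must be lists with fields kel and/or V",
               "lstgi_invalid")
    }
  }
  structure(
    list(n_compartments = n_compartments, ka = ka, kel = kel, k12 = k12,
         k21 = k21, V = V, per_dose = per_dose, unit_scale = unit_scale),
    class = "pk_model"
  )
}

#' Dosing regimen
#'
#' @param time Dose times in days (non-negative, strictly increasing).
#' @param amount Dose amounts in mg per kg body weight (non-negative).
#' @param route One of `"iv"`, `"ip"`, `"po"`, recycled across events.
#'   `iv` doses enter the central compartment as a bolus; `ip` and `po`
#'   doses enter a depot absorbed at rate `ka`.
#' @return A tibble of class `dose_regimen` with columns `time`, `amount`,
#'   `route`.  A zero-row regimen denotes an untreated (control) arm.
#' @examples
#' dose_regimen(time = c(8, 12, 16), amount = 30, route = "iv")
#' @export
dose_regimen <- function(time = numeric(), amount = numeric(),
                         route = character()) {
  if (length(time) == 0) {
    out <- tibble(time = numeric(), amount = numeric(), route = character())
    return(structure(out, class = c("dose_regimen", class(out))))
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    ls_abort("dose times must be finite and non-negative", "lstgi_invalid")
  }
  if (is.unsorted(time, strictly = TRUE)) {
    ls_abort("dose times must be strictly increasing (no duplicates)",
             "lstgi_invalid")
  }
  amount <- rep_len(amount, length(time))
  route <- rep_len(route, length(time))
  if (any(amount < 0)) ls_abort("dose amounts must be >= 0", "lstgi_invalid")
  if (!all(route %in% c("iv", "ip", "po"))) {
    ls_abort("route must be one of 'iv', 'ip', 'po'", "lstgi_invalid")
  }
  out <- tibble(time = as.numeric(time), amount = as.numeric(amount),
                route = route)
  structure(out, class = c("dose_regimen", class(out)))
}

# Exponential-term decomposition of the concentration curve for one dose.
# Each row: t_dose, coef, rate, type (0: coef*e^(-rate*tau),
# 1: coef*tau*e^(-rate*tau)).  Standard bolus / Bateman macro-constants.
pk_dose_terms <- function(model, t_dose, amount, route) {
  kel <- model$kel
  V <- model$V
  if (!is.null(model$per_dose)) {
    key <- format(amount)
    ov <- model$per_dose[[key]]
    if (is.null(ov)) {
      ls_abort(sprintf(
        "dose level %s has no entry in the per-dose override map", key),
        "lstgi_pk_error")
    }
    if (!is.null(ov$kel)) kel <- ov$kel
    if (!is.null(ov$V)) V <- ov$V
  }
  scale <- model$unit_scale
  dv <- amount / V * scale
  if (model$n_compartments == 2) {
    s <- kel + model$k12 + model$k21
    pr <- kel * model$k21
    disc <- sqrt(max(s * s - 4 * pr, 0))
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    if (route == "iv") {
      Ac <- (alpha - model$k21) / (alpha - beta)
      Bc <- (model$k21 - beta) / (alpha - beta)
      return(cbind(t_dose = t_dose, coef = dv * c(Ac, Bc),
                   rate = c(alpha, beta), type = c(0, 0)))
    }
    ka <- model$ka
    if (is.null(ka)) {
      ls_abort("absorption route requires `ka` in the PK model",
               "lstgi_pk_error")
    }
    if (min(abs(ka - alpha), abs(ka - beta)) < 1e-8 * alpha) {
      ls_abort("absorption rate ka coincides with a disposition rate",
               "lstgi_pk_error")
    }
    c1 <- (model$k21 - alpha) / ((ka - alpha) * (beta - alpha))
    c2 <- (model$k21 - beta) / ((ka - beta) * (alpha - beta))
    c3 <- (model$k21 - ka) / ((alpha - ka) * (beta - ka))
    return(cbind(t_dose = t_dose, coef = dv * ka * c(c1, c2, c3),
                 rate = c(alpha, beta, ka), type = c(0, 0, 0)))
  }
  # one compartment
  if (route == "iv") {
    return(cbind(t_dose = t_dose, coef = dv, rate = kel, type = 0))
  }
  ka <- model$ka
  if (is.null(ka)) {
    ls_abort("absorption route requires `ka` in the PK model",
             "lstgi_pk_error")
  }
  if (abs(ka - kel) < 1e-10 * ka) {
    # Bateman limit as kel -> ka: C = dv * ka * tau * exp(-ka tau)
    return(cbind(t_dose = t_dose, coef = dv * ka, rate = ka, type = 1))
  }
  cbind(t_dose = t_dose, coef = dv * ka / (ka - kel) * c(1, -1),
        rate = c(kel, ka), type = c(0, 0))
}

#' Simulate a plasma concentration profile
#'
#' Builds the closed-form concentration curve for a linear compartmental
#' model under a dosing regimen by superposition of single-dose solutions
#' (bolus bi-/mono-exponentials and Bateman absorption curves).  The
#' returned profile carries exact point and cumulative-integral evaluators.
#'
#' @param model A [pk_model()].
#' @param regimen A [dose_regimen()]; empty for a drug-free profile.
#' @param t_last End of the time domain in days; must be at or after the
#'   last dose.
#' @return An object of class `concentration_profile` with elements
#'   `terms` (exponential-term matrix), `dose_times`, `t_last`, and
#'   closed-form evaluators `conc(t)` (ng/mL) and `auc(t)` =
#'   \eqn{\int_0^t C(s)\,ds} (ng day/mL).
#' @examples
#' pk <- pk_model(2, kel = 0.868 * 24, k12 = 0.006 * 24, k21 = 0.0838 * 24,
#'                V = 0.81)
#' reg <- dose_regimen(time = c(8, 12, 16), amount = 30, route = "iv")
#' prof <- simulate_concentration(pk, reg, t_last = 40)
#' max(concentration(prof, seq(0, 40, by = 0.001)))
#' @export
simulate_concentration <- function(model, regimen, t_last) {
  stopifnot(inherits(model, "pk_model"))
  check_number(t_last, "t_last", lower = 0)
  if (!inherits(regimen, "dose_regimen")) {
    regimen <- do.call(dose_regimen, as.list(regimen))
  }
  if (nrow(regimen) > 0 && t_last < max(regimen$time)) {
    ls_abort("`t_last` must be at or after the last dose time",
             "lstgi_invalid")
  }
  terms <- matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("t_dose", "coef", "rate", "type")))
  if (nrow(regimen) > 0) {
    rows <- lapply(seq_len(nrow(regimen)), function(i) {
      pk_dose_terms(model, regimen$time[i], regimen$amount[i],
                    regimen$route[i])
    })
    terms <- do.call(rbind, rows)
  }
  structure(
    list(terms = terms, dose_times = regimen$time, t_last = t_last,
         model = model, regimen = regimen),
    class = "concentration_profile"
  )
}

#' Evaluate plasma concentration
#'
#' @param profile A [simulate_concentration()] result.
#' @param t Times in days (vectorized); concentration is 0 before the first
#'   dose and at a bolus time takes the post-dose (right-limit) value.
#' @return Concentrations in ng/mL.
#' @export
concentration <- function(profile, t) {
  stopifnot(inherits(profile, "concentration_profile"))
  tm <- profile$terms
  if (nrow(tm) == 0) return(rep(0, length(t)))
  out <- vapply(t, function(tt) {
    tau <- tt - tm[, "t_dose"]
    on <- tau >= 0
    if (!any(on)) return(0)
    e <- exp(-tm[on, "rate"] * tau[on])
    val <- sum(ifelse(tm[on, "type"] == 0, tm[on, "coef"] * e,
                      tm[on, "coef"] * tau[on] * e))
    max(val, 0)
  }, numeric(1))
  out
}

# cumulative integral of one exponential term from its dose time to tau
term_auc <- function(coef, rate, type, tau) {
  if (tau <= 0) return(0)
  if (type == 0) coef / rate * (1 - exp(-rate * tau))
  else coef / rate^2 * (1 - (1 + rate * tau) * exp(-rate * tau))
}

#' Cumulative drug exposure over an interval
#'
#' Computes \eqn{\int_{t_0}^{t_1} C(s)\,ds} from the closed-form
#' antiderivative of the profile.  Time before 0 contributes nothing (no
#' drug is present before the experiment starts).
#'
#' @param profile A [simulate_concentration()] result.
#' @param t0,t1 Interval bounds in days with `t0 <= t1 <= t_last`.
#' @return Exposure in ng day/mL (non-negative).
#' @export
cumulative_exposure <- function(profile, t0, t1) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (t1 < t0) ls_abort("`t1` must be >= `t0`", "lstgi_invalid")
  if (t1 > profile$t_last + 1e-9) {
    ls_abort("interval extends beyond the profile time domain",
             "lstgi_invalid")
  }
  t0 <- max(t0, 0)
  t1 <- max(t1, 0)
  tm <- profile$terms
  if (nrow(tm) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(tm))) {
    total <- total +
      term_auc(tm[i, "coef"], tm[i, "rate"], tm[i, "type"],
               t1 - tm[i, "t_dose"]) -
      term_auc(tm[i, "coef"], tm[i, "rate"], tm[i, "type"],
               t0 - tm[i, "t_dose"])
  }
  max(total, 0)
}

#' @export
print.concentration_profile <- function(x, ...) {
  nd <- length(x$dose_times)
  cat(sprintf(
    "<concentration_profile> %d dose(s), domain [0, %g] day\n", nd,
    x$t_last))
  if (nd > 0) {
    cat("  dose times (day):", paste(signif(x$dose_times, 4),
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
autoplot.concentration_profile <- function(object, n = 1001, ...) {
  tg <- sort(unique(c(seq(0, object$t_last, length.out = n),
                      object$dose_times)))
  df <- tibble(time = tg, conc = concentration(object, tg))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (day)", y = "Plasma concentration (ng/mL)")
}
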