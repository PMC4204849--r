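#' Model specification for fitting tumor growth data
#'
#' Bundles the structural model (growth parameters, optional drug effect,
#' PK model and per-arm dosing regimens) used by the fitting functions.
#' Observed data are long-format tibbles with columns `arm`, `time_day`
#' and `volume`; each arm is matched by name to an entry of `regimens`
#' (an arm without an entry, or with an empty regimen, is a control arm
#' simulated with the unperturbed model).
#'
#' @param growth A [growth_parameters()] object (current values double as
#'   fixed values and default starting values).
#' @param drug Optional [drug_effect_spec()].
#' @param pk Optional [pk_model()]; required when any arm has doses.
#' @param regimens Named list of [dose_regimen()] objects keyed by arm.
#' @param form Efficiency form override (see [division_efficiency()]).
#' @param p_of_total Evaluate `p` at `M + A` (default) or `M` only.
#' @param hmax Integrator step override used while fitting; the default
#'   (`NULL`) keeps the simulators' fine default step.  A coarser step
#'   (e.g. `T/30`) is accurate to well below measurement noise and several
#'   times faster, which matters inside a grid search.
#' @return An object of class `tgi_model_spec`.
#' @export
tgi_model_spec <- function(growth, drug = NULL, pk = NULL, regimens = NULL,
                           form = NULL, p_of_total = TRUE, hmax = NULL) {
  stopifnot(inherits(growth, "growth_parameters"))
  if (!is.null(drug)) stopifnot(inherits(drug, "drug_effect_spec"))
  if (!is.null(pk)) stopifnot(inherits(pk, "pk_model"))
  structure(list(growth = growth, drug = drug, pk = pk,
                 regimens = regimens, form = form,
                 p_of_total = p_of_total, hmax = hmax),
            class = "tgi_model_spec")
}

#' Fitting configuration
#'
#' @param free Character vector of free parameter names (growth:
#'   `p0`, `kin0`, `wth`, `pwth`, `w0`; drug: `k2`, `Emax`, `EC50`;
#'   reference model: `lambda1`, `k1`, `k2`).
#' @param start Optional named list of starting values (defaults are taken
#'   from the model spec).
#' @param lower,upper Optional named bound overrides.  Defaults: `p0` in
#'   \[1, 2\], `Emax` in \[0, 1\], every other parameter positive.
#' @param grid_T,grid_TA Grid for the lifespan parameters: either a numeric
#'   vector of nodes or a list with `min`, `max`, `step`.
#' @param refine After the coarse scan, rescan a `fine_step` lattice within
#'   one coarse step of the best node (the fine lattice is aligned to
#'   absolute multiples of `fine_step` so that refined estimates are
#'   reproducible regardless of the coarse anchor).
#' @param fine_step Fine lattice step in days (default 0.002).
#' @param weighting `"unweighted"` residuals (default) or `"proportional"`
#'   (residuals divided by the model prediction).
#' @param n_starts Number of jittered multi-starts for a continuous fit
#'   (applied at stand-alone fits and at the winning grid node; interior
#'   grid nodes reuse the previous node's estimates as a warm start).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param seed Seed for the multi-start jitter stream.
#' @param jitter_sd Standard deviation of the multi-start jitter on the
#'   transformed (unconstrained) parameter scale.
#' @param regrid_T Also grid-search `T` (not only `TA`) in the treated-arm
#'   stage of [fit_tgi_workflow()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = NULL, start = NULL, lower = NULL,
                       upper = NULL, grid_T = NULL, grid_TA = NULL,
                       refine = TRUE, fine_step = 0.002,
                       weighting = c("unweighted", "proportional"),
                       n_starts = 5L, max_iter = 50L, seed = 1L,
                       jitter_sd = 0.2, regrid_T = FALSE) {
  weighting <- match.arg(weighting)
  structure(list(free = free, start = start, lower = lower, upper = upper,
                 grid_T = grid_T, grid_TA = grid_TA, refine = refine,
                 fine_step = fine_step, weighting = weighting,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 jitter_sd = jitter_sd, regrid_T = regrid_T),
            class = "fit_config")
}

grid_nodes <- function(g, what) {
  if (is.null(g)) ls_abort(sprintf("no grid specified for %s", what),
                           "lstgi_invalid")
  if (is.numeric(g)) {
    if (length(g) < 1) ls_abort("empty grid", "lstgi_invalid")
    return(sort(unique(g)))
  }
  if (!all(c("min", "max", "step") %in% names(g)) || g$step <= 0) {
    ls_abort("grid spec must be a numeric vector or list(min, max, step > 0)",
             "lstgi_invalid")
  }
  seq(g$min, g$max, by = g$step)
}

# ---- parameter transforms ------------------------------------------------

default_bounds <- function(name) {
  switch(name,
         p0 = c(1, 2),
         Emax = c(0, 1),
         c(0, Inf))
}

make_transforms <- function(free, lower = NULL, upper = NULL) {
  lapply(setNames(free, free), function(nm) {
    b <- default_bounds(nm)
    lo <- lower[[nm]] %||% b[1]
    hi <- upper[[nm]] %||% b[2]
    if (is.finite(hi)) {
      list(lo = lo, hi = hi,
           fwd = function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo),
                                                     1e-12), 1 - 1e-12)),
           bwd = function(z) lo + (hi - lo) * stats::plogis(z))
    } else {
      list(lo = lo, hi = hi,
           fwd = function(x) log(pmax(x - lo, 1e-300)),
           bwd = function(z) lo + exp(z))
    }
  })
}

trans_fwd <- function(tr, theta) {
  vapply(names(tr), function(nm) tr[[nm]]$fwd(theta[[nm]]), numeric(1))
}
trans_bwd <- function(tr, z) {
  vapply(names(tr), function(nm) tr[[nm]]$bwd(z[[nm]]), numeric(1))
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# ---- predictors ----------------------------------------------------------

arm_regimen <- function(spec, arm) {
  reg <- spec$regimens[[arm]]
  if (is.null(reg)) reg <- dose_regimen()
  reg
}

update_growth <- function(growth, theta) {
  for (nm in intersect(names(theta),
                       c("T", "kin0", "w0", "p0", "wth", "psi", "pwth"))) {
    growth[[nm]] <- unname(theta[[nm]])
  }
  growth
}

update_drug <- function(drug, theta) {
  if (is.null(drug)) return(NULL)
  for (nm in intersect(names(theta), c("TA", "k2", "Emax", "EC50"))) {
    drug[[nm]] <- unname(theta[[nm]])
  }
  drug
}

# predictor closure: theta (named numeric) -> predicted volumes for `data`
build_predictor <- function(spec, data) {
  arms <- split(seq_len(nrow(data)), data$arm)
  arm_info <- lapply(names(arms), function(a) {
    idx <- arms[[a]]
    times <- data$time_day[idx]
    t_last <- max(times)
    reg <- arm_regimen(spec, a)
    treated <- nrow(reg) > 0
    profile <- if (treated) {
      if (is.null(spec$pk)) {
        ls_abort(sprintf("arm '%s' has doses but the spec has no PK model",
                         a), "lstgi_invalid")
      }
      simulate_concentration(spec$pk, reg, t_last)
    } else NULL
    list(arm = a, idx = idx, times = times, t_last = t_last,
         treated = treated, profile = profile)
  })
  function(theta) {
    growth <- update_growth(spec$growth, theta)
    drug <- update_drug(spec$drug, theta)
    pred <- numeric(nrow(data))
    for (ai in arm_info) {
      traj <- if (ai$treated) {
        if (is.null(drug)) {
          ls_abort("treated arm present but no drug effect in the spec",
                   "lstgi_invalid")
        }
        simulate_tgi(growth, drug, ai$profile, ai$t_last,
                     times = ai$times, form = spec$form,
                     hmax = spec$hmax, p_of_total = spec$p_of_total)
      } else {
        simulate_tumor_growth(growth, ai$t_last, times = ai$times,
                              form = spec$form, hmax = spec$hmax)
      }
      pred[ai$idx] <- traj$w
    }
    pred
  }
}

build_predictor_simeoni <- function(params, pk, regimens, data) {
  arms <- split(seq_len(nrow(data)), data$arm)
  arm_info <- lapply(names(arms), function(a) {
    idx <- arms[[a]]
    times <- data$time_day[idx]
    t_last <- max(times)
    reg <- regimens[[a]] %||% dose_regimen()
    profile <- simulate_concentration(
      pk %||% pk_model(1, kel = 1, V = 1), reg, t_last)
    list(idx = idx, times = times, t_last = t_last, profile = profile)
  })
  function(theta) {
    p <- params
    for (nm in intersect(names(theta), c("lambda1", "k1", "k2", "w0"))) {
      p[[nm]] <- unname(theta[[nm]])
    }
    pr <- simeoni_params(p$lambda1, p$k1, p$k2, p$w0, p$n_transit)
    pred <- numeric(nrow(data))
    for (ai in arm_info) {
      traj <- simulate_simeoni(pr, ai$profile, ai$t_last, times = ai$times)
      pred[ai$idx] <- traj$w
    }
    pred
  }
}

# ---- core nonlinear least squares ---------------------------------------

spec_defaults <- function(spec) {
  g <- spec$growth
  d <- spec$drug
  vals <- c(T = g$T, kin0 = g$kin0, w0 = g$w0, p0 = g$p0 %||% NA,
            wth = g$wth %||% NA, psi = g$psi, pwth = g$pwth %||% NA)
  if (!is.null(d)) {
    vals <- c(vals, TA = d$TA, k2 = d$k2 %||% NA, Emax = d$Emax %||% NA,
              EC50 = d$EC50 %||% NA)
  }
  vals[!is.na(vals)]
}

fit_nls_core <- function(obs, predictor, free, start_all, config) {
  tr <- make_transforms(free, config$lower, config$upper)
  start_free <- start_all[free]
  if (any(is.na(start_free))) {
    ls_abort(sprintf("no starting value for parameter(s): %s",
                     paste(free[is.na(start_free)], collapse = ", ")),
             "lstgi_invalid")
  }
  n <- length(obs)
  proportional <- config$weighting == "proportional"
  resid_fun <- function(z) {
    theta <- start_all
    theta[free] <- trans_bwd(tr, setNames(z, free))
    pred <- tryCatch(predictor(theta), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e8, n))
    if (proportional) (obs - pred) / pmax(pred, 1e-12) else obs - pred
  }
  z0 <- trans_fwd(tr, as.list(start_free))
  jitters <- with_local_seed(config$seed, {
    nj <- max(config$n_starts - 1L, 0L)
    if (nj > 0) matrix(rnorm(nj * length(free), sd = config$jitter_sd),
                       nrow = nj) else matrix(numeric(0), nrow = 0,
                                              ncol = length(free))
  })
  starts <- rbind(z0, sweep(jitters, 2, z0, `+`))
  best <- NULL
  for (si in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[si, ], fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iter, ptol = 1e-10,
                           ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(list(converged = FALSE, estimates = start_free, ssr = Inf,
                residuals = rep(NA_real_, n), se = NULL))
  }
  est <- trans_bwd(tr, setNames(best$par, free))
  theta_hat <- start_all
  theta_hat[free] <- est
  pred <- predictor(theta_hat)
  r <- if (proportional) (obs - pred) / pmax(pred, 1e-12) else obs - pred
  ssr <- sum(r^2)
  # asymptotic covariance from a central-difference Jacobian of the
  # (weighted) predictions with respect to the natural-scale parameters
  J <- matrix(NA_real_, n, length(free))
  for (j in seq_along(free)) {
    nm <- free[j]
    hstep <- max(abs(est[j]) * 1e-5, 1e-10)
    up <- theta_hat; up[nm] <- up[nm] + hstep
    dn <- theta_hat; dn[nm] <- dn[nm] - hstep
    pu <- tryCatch(predictor(up), error = function(e) rep(NA_real_, n))
    pd <- tryCatch(predictor(dn), error = function(e) rep(NA_real_, n))
    dp <- (pu - pd) / (2 * hstep)
    J[, j] <- if (proportional) dp / pmax(pred, 1e-12) else dp
  }
  se <- rep(NA_real_, length(free))
  cond <- NA_real_
  if (all(is.finite(J))) {
    jtj <- crossprod(J)
    cond <- kappa(jtj, exact = TRUE)
    s2 <- ssr / max(n - length(free), 1)
    cov <- tryCatch(s2 * solve(jtj), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  list(converged = best$info %in% 1:4, estimates = setNames(est, free),
       ssr = ssr, residuals = r, predicted = pred, se = setNames(se, free),
       jtj_condition = cond, niter = best$niter, info = best$info)
}

#' Fit continuous model parameters by nonlinear least squares
#'
#' Minimizes the sum of squared residuals between observed and predicted
#' tumor sizes over the free continuous parameters, with the lifespans `T`
#' and `TA` held fixed (they enter the model through an integer-part
#' recursion depth and are therefore not continuously identifiable by a
#' gradient method).  Bounds are enforced through smooth transforms (log
#' for positive parameters, scaled logit for interval-bounded ones) and the
#' optimum is polished from several jittered starting points.  Parameter
#' precision is reported as CV% = 100 SE / estimate with standard errors
#' from the Jacobian-based asymptotic covariance \eqn{s^2 (J^T J)^{-1}}.
#'
#' @param data Tibble with columns `arm`, `time_day`, `volume`.
#' @param spec A [tgi_model_spec()].
#' @param config A [fit_config()]; `config$free` names the free
#'   parameters.
#' @return An object of class `tgi_fit` with fields `estimates`, `cv_pct`,
#'   `ssr`, `residuals`, `fitted` (observed-vs-predicted tibble), `fixed`,
#'   and convergence information.  Use [tidy()] / [glance()] to extract
#'   tidy summaries.
#' @export
fit_tgi_continuous <- function(data, spec, config) {
  stopifnot(inherits(spec, "tgi_model_spec"), inherits(config, "fit_config"))
  data <- validate_obs(data)
  free <- config$free
  if (is.null(free) || length(free) < 1) {
    ls_abort("`config$free` must name at least one free parameter",
             "lstgi_invalid")
  }
  if (nrow(data) < length(free) + 1) {
    ls_abort("need at least one more observation than free parameters",
             "lstgi_invalid")
  }
  predictor <- build_predictor(spec, data)
  start_all <- spec_defaults(spec)
  for (nm in names(config$start %||% list())) {
    start_all[nm] <- config$start[[nm]]
  }
  res <- fit_nls_core(data$volume, predictor, free, start_all, config)
  new_tgi_fit(res, data, spec, config, free, start_all)
}

new_tgi_fit <- function(res, data, spec, config, free, start_all) {
  fixed <- start_all[setdiff(names(start_all), free)]
  fitted_tbl <- tibble(arm = data$arm, time_day = data$time_day,
                       observed = data$volume,
                       predicted = res$predicted %||%
                         rep(NA_real_, nrow(data)))
  cv <- 100 * res$se / abs(res$estimates)
  structure(
    list(estimates = res$estimates, se = res$se, cv_pct = cv,
         ssr = res$ssr, residuals = res$residuals, fitted = fitted_tbl,
         fixed = fixed, converged = res$converged,
         jtj_condition = res$jtj_condition %||% NA_real_,
         n_obs = nrow(data), free = free, spec = spec, config = config),
    class = "tgi_fit")
}

validate_obs <- function(data) {
  data <- as_tibble(data)
  need <- c("arm", "time_day", "volume")
  if (!all(need %in% names(data))) {
    ls_abort(sprintf("observations must have columns %s",
                     paste(need, collapse = ", ")), "lstgi_invalid")
  }
  if (any(!is.finite(data$volume)) || any(data$volume <= 0)) {
    ls_abort("volumes must be finite and positive", "lstgi_invalid")
  }
  data
}

#' @export
print.tgi_fit <- function(x, ...) {
  cat("<tgi_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf(" SSR = %.6g on %d observations\n", x$ssr, x$n_obs))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.tgi_fit <- function(x, ...) {
  free_tbl <- tibble(term = names(x$estimates),
                     estimate = unname(x$estimates),
                     cv_pct = unname(x$cv_pct), fixed = FALSE)
  fixed_tbl <- tibble(term = names(x$fixed), estimate = unname(x$fixed),
                      cv_pct = NA_real_, fixed = TRUE)
  dplyr::bind_rows(free_tbl, fixed_tbl)
}

#' @export
glance.tgi_fit <- function(x, ...) {
  tibble(ssr = x$ssr, n_obs = x$n_obs, n_free = length(x$free),
         sigma = sqrt(x$ssr / max(x$n_obs - length(x$free), 1)),
         converged = x$converged, jtj_condition = x$jtj_condition)
}

#' @export
autoplot.tgi_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(x = .data$time_day, colour = .data$arm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted)) +
    ggplot2::labs(x = "Time (day)", y = "Tumor size", colour = NULL)
}

# ---- grid search over the lifespan parameters ---------------------------

refine_lattice <- function(best, coarse_step, fine_step, lo, hi) {
  from <- max(lo, best - coarse_step)
  to <- min(hi, best + coarse_step)
  # align to absolute multiples of fine_step for reproducible nodes
  from <- ceiling(from / fine_step - 1e-9) * fine_step
  nodes <- seq(from, to + 1e-12, by = fine_step)
  nodes[nodes >= lo - 1e-12 & nodes <= hi + 1e-12]
}

#' Grid search over the lifespan parameters
#'
#' Scans a grid of `T` (and optionally `TA`) nodes; at each node the free
#' continuous parameters are re-estimated by [fit_tgi_continuous()] (warm
#' started from the previous node) and the node with the smallest SSR
#' wins, ties broken toward smaller `T`, then smaller `TA`.  With
#' `config$refine = TRUE` the scan is repeated on a fine lattice around
#' the coarse winner.
#'
#' @inheritParams fit_tgi_continuous
#' @param search `"T"`, `"TA"`, or `"both"`.
#' @return A list of class `tgi_grid_search`: `best_T`, `best_TA`,
#'   `best_fit` (the refit at the winning node), and `trace` (tibble with
#'   one row per node: `T`, `TA`, `ssr`, `converged`, `stage`).
#' @export
grid_search_lifespans <- function(data, spec, config,
                                  search = c("T", "TA", "both")) {
  search <- match.arg(search)
  data <- validate_obs(data)
  want_T <- search %in% c("T", "both")
  want_TA <- search %in% c("TA", "both")
  T_nodes <- if (want_T) grid_nodes(config$grid_T, "T") else spec$growth$T
  TA_nodes <- if (want_TA) grid_nodes(config$grid_TA, "TA")
              else if (!is.null(spec$drug)) spec$drug$TA else NA_real_

  scan <- function(Tn, TAn, warm, stage) {
    nodes <- expand.grid(T = Tn, TA = TAn)
    nodes <- nodes[order(nodes$T, nodes$TA), , drop = FALSE]
    trace <- vector("list", nrow(nodes))
    best <- NULL
    start_theta <- warm
    for (i in seq_len(nrow(nodes))) {
      sp <- spec
      sp$growth$T <- nodes$T[i]
      if (!is.null(sp$drug) && !is.na(nodes$TA[i])) {
        sp$drug$TA <- nodes$TA[i]
      }
      cfg <- config
      cfg$start <- start_theta
      cfg$n_starts <- if (i == 1) config$n_starts else 1L
      fit <- tryCatch(fit_tgi_continuous(data, sp, cfg),
                      error = function(e) NULL)
      ok <- !is.null(fit) && is.finite(fit$ssr)
      trace[[i]] <- tibble(T = nodes$T[i], TA = nodes$TA[i],
                           ssr = if (ok) fit$ssr else Inf,
                           converged = ok && fit$converged, stage = stage)
      if (ok) {
        start_theta <- as.list(fit$estimates) # warm start for the next node
        # strict improvement: nodes are scanned in (T, TA) order, so the
        # first minimum wins ties toward smaller T, then smaller TA
        if (is.null(best) || fit$ssr < best$fit$ssr) {
          best <- list(T = nodes$T[i], TA = nodes$TA[i], fit = fit)
        }
      }
    }
    list(best = best, trace = dplyr::bind_rows(trace),
         warm = start_theta)
  }

  warm0 <- config$start %||% list()
  coarse <- scan(T_nodes, TA_nodes, warm0, "coarse")
  if (is.null(coarse$best)) {
    ls_abort("no grid node converged", "lstgi_fit_error")
  }
  trace <- coarse$trace
  best <- coarse$best
  if (isTRUE(config$refine)) {
    stepT <- if (want_T && length(T_nodes) > 1) min(diff(sort(T_nodes)))
             else 0
    stepA <- if (want_TA && length(TA_nodes) > 1) min(diff(sort(TA_nodes)))
             else 0
    fT <- if (want_T && stepT > config$fine_step) {
      refine_lattice(best$T, stepT, config$fine_step, min(T_nodes),
                     max(T_nodes))
    } else best$T
    fA <- if (want_TA && stepA > config$fine_step) {
      refine_lattice(best$TA, stepA, config$fine_step, min(TA_nodes),
                     max(TA_nodes))
    } else best$TA
    if (length(fT) > 1 && length(fA) > 1) {
      # refine the two lifespans coordinate-wise (a joint fine lattice
      # would be quadratically larger for no practical gain)
      fine1 <- scan(best$T, fA, as.list(best$fit$estimates), "fine_TA")
      trace <- dplyr::bind_rows(trace, fine1$trace)
      if (!is.null(fine1$best) && fine1$best$fit$ssr <= best$fit$ssr) {
        best <- fine1$best
      }
      fine2 <- scan(fT, best$TA, as.list(best$fit$estimates), "fine_T")
      trace <- dplyr::bind_rows(trace, fine2$trace)
      if (!is.null(fine2$best) && fine2$best$fit$ssr <= best$fit$ssr) {
        best <- fine2$best
      }
    } else if (length(fT) > 1 || length(fA) > 1) {
      fine <- scan(fT, fA, as.list(best$fit$estimates), "fine")
      trace <- dplyr::bind_rows(trace, fine$trace)
      if (!is.null(fine$best) && fine$best$fit$ssr <= best$fit$ssr) {
        best <- fine$best
      }
    }
  }
  # polish the winner with the full multi-start budget
  sp <- spec
  sp$growth$T <- best$T
  if (!is.null(sp$drug) && !is.na(best$TA)) sp$drug$TA <- best$TA
  cfg <- config
  cfg$start <- as.list(best$fit$estimates)
  final <- fit_tgi_continuous(data, sp, cfg)
  if (final$ssr > best$fit$ssr) final <- best$fit
  structure(list(best_T = best$T, best_TA = best$TA, best_fit = final,
                 trace = trace),
            class = "tgi_grid_search")
}

#' @export
print.tgi_grid_search <- function(x, ...) {
  cat(sprintf("<tgi_grid_search> best T = %g, TA = %s, SSR = %.6g (%d nodes)\n",
              x$best_T, format(x$best_TA), x$best_fit$ssr, nrow(x$trace)))
  invisible(x)
}

# ---- sequential workflow -------------------------------------------------

#' Sequential control-then-treated fitting workflow
#'
#' Reproduces the staged estimation procedure used for xenograft TGI
#' studies:
#' 1. **Control stage** -- grid search over `T` with the growth parameters
#'    refit at each node, on the control arm only.
#' 2. **Treated stage** -- growth parameters fixed at their control-stage
#'    values, grid search over `TA` (optionally jointly over `T` with
#'    `config$regrid_T = TRUE`), drug parameters refit at each node on the
#'    treated arms jointly.
#' 3. **Simultaneous stage** (optional) -- with `T` and `TA` fixed at the
#'    grid winners, all continuous growth and drug parameters are refit on
#'    control and treated arms together.
#'
#' @inheritParams fit_tgi_continuous
#' @param control_arm Name of the control arm in `data` (default: any arm
#'   with no dosing regimen).
#' @param free_growth,free_drug Free parameter names for the control and
#'   treated stages; defaults depend on the growth mode and effect form.
#' @param simultaneous Run stage 3 (default `TRUE` when treated arms are
#'   present).
#' @param joint_grid Replace stages 2-3 by a single grid search over
#'   `(T, TA)` on all arms with the growth and drug continuous parameters
#'   refit jointly at every node (warm-started from stage 1).  This keeps
#'   the lifespans and the continuous parameters mutually consistent and
#'   is the recommended mode for sparse designs, at a higher cost.
#' @return An object of class `tgi_workflow` with elements `stage1`,
#'   `stage2`, `stage3` (possibly `NULL`), and `estimates`, the final
#'   parameter table.
#' @export
fit_tgi_workflow <- function(data, spec, config, control_arm = NULL,
                             free_growth = NULL, free_drug = NULL,
                             simultaneous = TRUE, joint_grid = FALSE) {
  data <- validate_obs(data)
  arms <- unique(data$arm)
  has_doses <- vapply(arms, function(a) nrow(arm_regimen(spec, a)) > 0,
                      logical(1))
  control_arm <- control_arm %||% arms[!has_doses][1]
  if (is.na(control_arm) || !control_arm %in% arms) {
    ls_abort("no control arm found", "lstgi_invalid")
  }
  treated_arms <- setdiff(arms[has_doses], control_arm)

  free_growth <- free_growth %||% switch(spec$growth$mode,
    full = c("p0", "kin0", "wth"),
    linear_phase = c("pwth", "kin0"),
    constant_p = c("p0", "kin0"))
  free_drug <- free_drug %||% {
    if (is.null(spec$drug)) character()
    else if (spec$drug$effect_form == "linear") "k2"
    else c("Emax", "EC50")
  }

  # stage 1: control arm, grid over T
  cfg1 <- config
  cfg1$free <- free_growth
  control_data <- data[data$arm == control_arm, , drop = FALSE]
  stage1 <- grid_search_lifespans(control_data, spec, cfg1, search = "T")

  spec1 <- spec
  spec1$growth <- update_growth(spec$growth, stage1$best_fit$estimates)
  spec1$growth$T <- stage1$best_T

  if (length(treated_arms) == 0) {
    est <- c(T = stage1$best_T, stage1$best_fit$estimates)
    return(structure(list(stage1 = stage1, stage2 = NULL, stage3 = NULL,
                          estimates = est, control_arm = control_arm,
                          spec = spec1),
                     class = "tgi_workflow"))
  }
  if (is.null(spec$drug)) {
    ls_abort("treated arms present but the spec has no drug effect",
             "lstgi_invalid")
  }

  # stage 2: either drug parameters alone on the treated arms with the
  # growth stage fixed, or (joint_grid) every continuous parameter refit
  # at each (T, TA) node on all arms
  cfg2 <- config
  if (isTRUE(joint_grid)) {
    cfg2$free <- c(free_growth, free_drug)
    cfg2$start <- as.list(stage1$best_fit$estimates)
    stage2 <- grid_search_lifespans(data, spec1, cfg2, search = "both")
  } else {
    cfg2$free <- free_drug
    treated_data <- data[data$arm %in% treated_arms, , drop = FALSE]
    stage2 <- grid_search_lifespans(
      treated_data, spec1, cfg2,
      search = if (isTRUE(config$regrid_T)) "both" else "TA")
  }

  spec2 <- spec1
  spec2$growth$T <- stage2$best_T %||% stage1$best_T
  spec2$drug <- update_drug(spec2$drug, stage2$best_fit$estimates)
  spec2$drug$TA <- stage2$best_TA

  stage3 <- NULL
  final_fit <- stage2$best_fit
  if (isTRUE(joint_grid)) {
    spec2$growth <- update_growth(spec2$growth, stage2$best_fit$estimates)
    est <- c(T = spec2$growth$T, TA = spec2$drug$TA, final_fit$estimates)
    return(structure(list(stage1 = stage1, stage2 = stage2, stage3 = NULL,
                          estimates = est, control_arm = control_arm,
                          spec = spec2),
                     class = "tgi_workflow"))
  }
  if (isTRUE(simultaneous)) {
    cfg3 <- config
    cfg3$free <- c(free_growth, free_drug)
    cfg3$start <- c(as.list(stage1$best_fit$estimates),
                    as.list(stage2$best_fit$estimates))
    stage3 <- fit_tgi_continuous(data, spec2, cfg3)
    final_fit <- stage3
  }
  est <- c(T = spec2$growth$T, TA = spec2$drug$TA, final_fit$estimates)
  if (is.null(stage3)) {
    est <- c(est, stage1$best_fit$estimates)
  }
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 estimates = est, control_arm = control_arm, spec = spec2),
            class = "tgi_workflow")
}

#' @export
print.tgi_workflow <- function(x, ...) {
  cat("<tgi_workflow>\n  estimates:\n")
  print(round(x$estimates, 6))
  invisible(x)
}

#' @export
tidy.tgi_workflow <- function(x, ...) {
  fit <- x$stage3 %||% (x$stage2 %||% x$stage1)$best_fit %||%
    x$stage1$best_fit
  gridded <- tibble(term = c("T", "TA")[c(TRUE, !is.null(x$stage2))],
                    estimate = c(x$spec$growth$T,
                                 if (!is.null(x$stage2))
                                   x$spec$drug$TA),
                    cv_pct = NA_real_, fixed = TRUE)
  dplyr::bind_rows(gridded, tidy(fit))
}

# ---- reference-model fit and model comparison ---------------------------

#' Fit the linearized reference model
#'
#' @param data Observations tibble (`arm`, `time_day`, `volume`).
#' @param params Starting [simeoni_params()].
#' @param pk A [pk_model()] for the treated arms.
#' @param regimens Named list of [dose_regimen()] per arm.
#' @param config A [fit_config()]; default free parameters are
#'   `lambda1`, `k1`, `k2`.
#' @return A `tgi_fit` object.
#' @export
fit_simeoni <- function(data, params, pk, regimens, config) {
  data <- validate_obs(data)
  free <- config$free %||% c("lambda1", "k1", "k2")
  config$free <- free
  predictor <- build_predictor_simeoni(params, pk, regimens, data)
  start_all <- c(lambda1 = params$lambda1, k1 = params$k1, k2 = params$k2,
                 w0 = params$w0)
  for (nm in names(config$start %||% list())) {
    start_all[nm] <- config$start[[nm]]
  }
  res <- fit_nls_core(data$volume, predictor, free, start_all, config)
  spec <- structure(list(growth = NULL, drug = NULL, pk = pk,
                         regimens = regimens, reference = params),
                    class = "tgi_model_spec")
  new_tgi_fit(res, data, spec, config, free, start_all)
}

#' Head-to-head comparison of the lifespan and reference models
#'
#' Fits the lifespan TGI workflow and the linearized reference model to the
#' same dataset and tabulates the drug potency estimates.
#'
#' @inheritParams fit_tgi_workflow
#' @param reference_start Starting [simeoni_params()] for the reference
#'   fit.
#' @param reference_config Optional separate [fit_config()] for the
#'   reference fit.
#' @return A list of class `tgi_comparison`: `lifespan` (workflow),
#'   `reference` (fit), and `potency` (tibble with both `k2` estimates and
#'   their ratio).
#' @export
compare_models <- function(data, spec, config, reference_start,
                           reference_config = NULL, ...) {
  wf <- fit_tgi_workflow(data, spec, config, ...)
  ref_cfg <- reference_config %||% fit_config(
    free = c("lambda1", "k1", "k2"), weighting = config$weighting,
    n_starts = config$n_starts, max_iter = config$max_iter,
    seed = config$seed)
  ref <- fit_simeoni(data, reference_start, spec$pk, spec$regimens,
                     ref_cfg)
  k2_ls <- unname(wf$estimates["k2"])
  k2_ref <- unname(ref$estimates["k2"])
  potency <- tibble(model = c("lifespan", "reference"),
                    k2 = c(k2_ls, k2_ref),
                    cv_pct = c(
                      if ("k2" %in% names(wf$stage3$cv_pct %||%
                                          wf$stage2$best_fit$cv_pct))
                        (wf$stage3 %||% wf$stage2$best_fit)$cv_pct[["k2"]]
                      else NA_real_,
                      ref$cv_pct[["k2"]]))
  structure(list(lifespan = wf, reference = ref, potency = potency,
                 k2_ratio = k2_ls / k2_ref),
            class = "tgi_comparison")
}

#' @export
print.tgi_comparison <- function(x, ...) {
  cat("<tgi_comparison> potency concordance\n")
  print(x$potency)
  cat(sprintf("  k2 ratio (lifespan / reference) = %.3f\n", x$k2_ratio))
  invisible(x)
}
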