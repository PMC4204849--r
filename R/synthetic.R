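#' Synthetic xenograft study design
#'
#' A study design couples arm definitions (label, dosing regimen,
#' observation schedule) with ground-truth model parameters and a noise
#' model, so that simulators and the full estimation workflow can be
#' exercised end to end with a known answer.
#'
#' @param arms A list; each element is a list with `label` (character),
#'   `regimen` (a [dose_regimen()]; empty for control) and `obs_times`
#'   (sorted non-negative days).
#' @param truth A list with elements `growth` ([growth_parameters()]),
#'   optional `drug` ([drug_effect_spec()]), optional `pk` ([pk_model()]),
#'   optional `form` and `p_of_total`.
#' @param noise_cv Proportional noise coefficient of variation (default
#'   0.05; xenograft volume errors scale with size).
#' @param noise_sd Additive noise standard deviation (default 0).
#' @param seed Integer seed; the same seed and design always regenerate
#'   the identical dataset.
#' @return An object of class `study_design`.
#' @export
study_design <- function(arms, truth, noise_cv = 0.05, noise_sd = 0,
                         seed = 1L) {
  stopifnot(is.list(arms), length(arms) >= 1)
  for (a in arms) {
    if (!all(c("label", "regimen", "obs_times") %in% names(a))) {
      ls_abort("each arm needs fields label, regimen, obs_times",
               "lstgi_invalid")
    }
    if (any(a$obs_times < 0) || is.unsorted(a$obs_times)) {
      ls_abort("observation times must be sorted and non-negative",
               "lstgi_invalid")
    }
  }
  stopifnot(inherits(truth$growth, "growth_parameters"))
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(arms = arms, truth = truth, noise_cv = noise_cv,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "study_design")
}

#' Case-study design templates
#'
#' Ready-made [study_design()]s emulating the three xenograft case-study
#' designs, with truth parameters set to the published fitted values so
#' they are biologically realistic fixtures:
#'
#' * `"paclitaxel"` -- HCT116 xenograft; control plus 30 mg/kg i.v. every
#'   4 days for 3 doses starting day 8; biphasic growth (grams) and a
#'   cycle-specific Emax effect with `Emax` fixed at 1.
#' * `"az968"` -- control plus 10/20/30 mg/kg i.p. weekly for 3 weeks;
#'   linear-phase growth (mm^3), non-cycle-specific linear effect, and
#'   dose-specific elimination/volume in a two-compartment absorption PK
#'   model.
#' * `"azd1208"` -- control plus 0.3/1/3/10/30 mg/kg p.o. once daily;
#'   exponential-only growth (threshold sentinel far above the data),
#'   doubling time fixed at 3 days, non-cycle-specific Emax effect, and a
#'   one-compartment oral PK model with `kel = ka`.
#'
#' @param name One of `"paclitaxel"`, `"az968"`, `"azd1208"`.
#' @param noise_cv,noise_sd,seed Passed to [study_design()].
#' @return A [study_design()].
#' @export
casestudy_template <- function(name = c("paclitaxel", "az968", "azd1208"),
                               noise_cv = 0.05, noise_sd = 0, seed = 1L) {
  name <- match.arg(name)
  d <- switch(name,
    paclitaxel = {
      obs <- seq(6, 39, by = 3)
      list(
        arms = list(
          list(label = "control", regimen = dose_regimen(),
               obs_times = obs),
          list(label = "paclitaxel_30",
               regimen = dose_regimen(time = c(8, 12, 16), amount = 30,
                                      route = "iv"),
               obs_times = obs)),
        truth = list(
          growth = growth_parameters("full", T = 1.46, kin0 = 4.04e-2,
                                     w0 = 0.033, p0 = 1.44, wth = 2.48),
          drug = drug_effect_spec("cycle_specific", "emax", TA = 0.536,
                                  Emax = 1, EC50 = 9.45),
          pk = pk_model(2, kel = 0.868 * 24, k12 = 0.006 * 24,
                        k21 = 0.0838 * 24, V = 0.81)))
    },
    az968 = {
      obs_c <- c(0.5, 2, 5, 7, 9, 12, 14, 16, 19)
      obs_t <- c(obs_c, 23) # extra measurement 216 h after the last dose
      weekly <- function(amt) dose_regimen(time = c(0, 7, 14),
                                           amount = amt, route = "ip")
      list(
        arms = list(
          list(label = "control", regimen = dose_regimen(),
               obs_times = obs_c),
          list(label = "az968_10", regimen = weekly(10), obs_times = obs_t),
          list(label = "az968_20", regimen = weekly(20), obs_times = obs_t),
          list(label = "az968_30", regimen = weekly(30),
               obs_times = obs_t)),
        truth = list(
          growth = growth_parameters("linear_phase", T = 1.28, kin0 = 49.9,
                                     w0 = 180, pwth = 80.8),
          drug = drug_effect_spec("non_cycle_specific", "linear",
                                  TA = 5.56, k2 = 2.30e-3),
          pk = pk_model(2, kel = 24.7, k12 = 8.74, k21 = 11.2, V = 1.97,
                        ka = 46.8,
                        per_dose = list(
                          "10" = list(kel = 33.9, V = 2.70),
                          "20" = list(kel = 26.0, V = 2.07),
                          "30" = list(kel = 24.7, V = 1.97)))))
    },
    azd1208 = {
      obs <- c(0.5, 2, 4, 7, 9, 11, 14, 16)
      daily <- function(amt) dose_regimen(time = 0:13, amount = amt,
                                          route = "po")
      list(
        arms = c(
          list(list(label = "control", regimen = dose_regimen(),
                    obs_times = obs)),
          lapply(c(0.3, 1, 3, 10, 30), function(amt) {
            list(label = sprintf("azd1208_%g", amt), regimen = daily(amt),
                 obs_times = obs)
          })),
        truth = list(
          # threshold sentinel far beyond any observable size makes the
          # growth purely exponential over the study window
          growth = growth_parameters("full", T = 3, kin0 = 27.8, w0 = 170,
                                     p0 = 1.57, wth = 1e12),
          drug = drug_effect_spec("non_cycle_specific", "emax", TA = 1.92,
                                  Emax = 0.159, EC50 = 182),
          pk = pk_model(1, kel = 5.52, ka = 5.52, V = 4.86)))
    })
  study_design(d$arms, d$truth, noise_cv = noise_cv, noise_sd = noise_sd,
               seed = seed)
}

#' Generate a synthetic xenograft dataset
#'
#' Simulates the appropriate model (unperturbed for control arms,
#' perturbed for treated arms) at each arm's observation times and applies
#' the noise model \eqn{y = \hat w (1 + CV\,\epsilon) + SD\,\epsilon'} with
#' independent standard-normal draws from the seeded stream; non-positive
#' draws are resampled and counted in the provenance record.
#'
#' @param design A [study_design()].
#' @return A list of class `synthetic_study` with elements `observations`
#'   (tibble `arm`, `time_day`, `volume`), `dosing` (tibble `arm`,
#'   `time_day`, `dose_mg_per_kg`, `route`), `truth_trajectories`
#'   (noise-free predictions), and `provenance` (truth parameters, seed,
#'   noise model, resample count).
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  truth <- design$truth
  resampled <- 0L
  obs_list <- list()
  dose_list <- list()
  truth_list <- list()
  with_local_seed(design$seed, {
    for (a in design$arms) {
      t_last <- max(a$obs_times, if (nrow(a$regimen)) max(a$regimen$time))
      if (nrow(a$regimen) > 0) {
        profile <- simulate_concentration(truth$pk, a$regimen, t_last)
        traj <- simulate_tgi(truth$growth, truth$drug, profile, t_last,
                             times = a$obs_times,
                             form = truth$form %||% NULL,
                             p_of_total = truth$p_of_total %||% TRUE)
        dose_list[[a$label]] <- tibble(
          arm = a$label, time_day = a$regimen$time,
          dose_mg_per_kg = a$regimen$amount, route = a$regimen$route)
      } else {
        traj <- simulate_tumor_growth(truth$growth, t_last,
                                      times = a$obs_times,
                                      form = truth$form %||% NULL)
      }
      what <- traj$w
      vol <- vapply(what, function(mu) {
        repeat {
          y <- mu * (1 + design$noise_cv * rnorm(1)) +
            design$noise_sd * rnorm(1)
          if (y > 0) return(y)
          resampled <<- resampled + 1L
        }
      }, numeric(1))
      obs_list[[a$label]] <- tibble(arm = a$label, time_day = a$obs_times,
                                    volume = vol)
      truth_list[[a$label]] <- tibble(arm = a$label,
                                      time_day = a$obs_times,
                                      volume = what)
    }
  })
  structure(
    list(observations = dplyr::bind_rows(obs_list),
         dosing = dplyr::bind_rows(dose_list),
         truth_trajectories = dplyr::bind_rows(truth_list),
         provenance = list(truth = truth, seed = design$seed,
                           noise_cv = design$noise_cv,
                           noise_sd = design$noise_sd,
                           resampled = resampled)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d arms, %d observations (seed %d)\n",
              length(unique(x$observations$arm)), nrow(x$observations),
              x$provenance$seed))
  invisible(x)
}

#' Model spec matching a study design
#'
#' Convenience constructor turning a [study_design()] into the
#' [tgi_model_spec()] used to fit its generated data (regimens keyed by
#' arm label, truth parameters as starting values).
#'
#' @param design A [study_design()].
#' @return A [tgi_model_spec()].
#' @export
design_model_spec <- function(design) {
  regimens <- lapply(design$arms, `[[`, "regimen")
  names(regimens) <- vapply(design$arms, `[[`, character(1), "label")
  tgi_model_spec(growth = design$truth$growth, drug = design$truth$drug,
                 pk = design$truth$pk, regimens = regimens,
                 form = design$truth$form %||% NULL,
                 p_of_total = design$truth$p_of_total %||% TRUE)
}
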