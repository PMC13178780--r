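# Per-patient outcome classification and recurrence times.
#
# With the viability term on, the initial burden partitions (0, Inf):
#   B0 >= omega_d        -> detectable at t = 0 (recurrence time 0)
#   eps_V < B0 < omega_d -> progression: the burden regrows and crosses
#                           omega_d at a finite recurrence time
#   B0 <= eps_V          -> cure: the burden decays to zero and the
#                           detection threshold is never reached
# (B0 = eps_V is an unstable equilibrium strictly below omega_d, hence
# never detected; B0 = omega_d recurs at t = 0 since detection uses >=.)

#' Classify a patient by initial burden
#'
#' @param B0 Initial burden(s), cc, `> 0`; vectorised.
#' @param eps_V Viability threshold, cc, `>= 0`.
#' @param omega_d Detection threshold, cc, `> eps_V`.
#'
#' @return A character vector in `{"detectable_at_t0", "progression",
#'   "cure"}`.
#' @export
#' @examples
#' classify_patient(c(0.005, 0.02, 0.06), eps_V = 0.01, omega_d = 0.056)
classify_patient <- function(B0, eps_V, omega_d) {
  if (!(eps_V >= 0 && eps_V < omega_d)) {
    abort_domain("requires 0 <= eps_V < omega_d.")
  }
  if (!is.numeric(B0) || any(!is.finite(B0)) || any(B0 <= 0)) {
    abort_domain("`B0` must be positive and finite.")
  }
  dplyr::case_when(
    B0 >= omega_d ~ "detectable_at_t0",
    B0 <= eps_V ~ "cure",
    TRUE ~ "progression"
  )
}

#' Recurrence indicator R_i(t)
#'
#' The per-patient step function: 1 once the burden has been detectable
#' (`t >= t_R`), 0 before and for cured patients (`t_R = NA`).
#' Right-continuous; the crossing instant itself counts as recurred.
#'
#' @param t_R Recurrence time in days, or `NA` for a cured patient.
#' @param t Evaluation time(s), days, `>= 0`; vectorised.
#'
#' @return Integer 0/1 vector, same length as `t`.
#' @export
recurrence_indicator <- function(t_R, t) {
  if (any(t < 0)) abort_domain("`t` must be non-negative.")
  as.integer(!is.na(t_R) & t >= t_R)
}

# Event-detecting ODE crossing time for the non-exponential laws:
# integrate until B(t) hits omega_d (terminal root).
ode_recurrence_time <- function(model, B0, K = NULL, horizon = 7300) {
  sol <- tryCatch(
    deSolve::ode(y = c(B = B0), times = c(0, horizon),
                 func = ode_deriv(model, K), parms = NULL, method = "lsodar",
                 rtol = 1e-10, atol = 1e-14,
                 rootfunc = function(t, y, parms) y[[1]] - model$omega_d),
    error = function(e) {
      rlang::abort(paste0("recurrence integration failed: ",
                          conditionMessage(e)),
                   class = "regrowr_integration_error")
    })
  troot <- attr(sol, "troot")
  if (!is.null(troot) && length(troot) > 0) troot[1] else NA_real_
}

#' Recurrence time for one patient
#'
#' Classifies the patient and, for progressors, finds the first time the
#' burden reaches the detection threshold: by the closed-form Bernoulli
#' solution for the exponential law, by adaptive ODE integration with
#' event detection for the logistic and Gompertz laws. With the
#' viability term disabled every patient with `B0 > 0` eventually
#' recurs; a crossing not reached within `horizon` is flagged
#' `"beyond_horizon"` rather than silently treated as cure.
#'
#' @param B0 Initial burden, cc, `> 0`.
#' @param model A [regrowth_model()].
#' @param K Optional per-patient carrying capacity.
#' @param horizon Follow-up horizon in days.
#'
#' @return A list with elements `outcome` (`"cure"`, `"progression"`,
#'   `"detectable_at_t0"` or `"beyond_horizon"`), `t_R` (days or `NA`)
#'   and `method` (`"closed_form"` or `"ode_event"`).
#' @export
#' @examples
#' m <- regrowth_model(growth_law("exponential", 0.0015), 0.01, 0.056)
#' patient_recurrence_time(0.02, m)
patient_recurrence_time <- function(B0, model, K = NULL, horizon = 7300) {
  stopifnot(inherits(model, "regrowth_model"))
  if (!is.numeric(B0) || length(B0) != 1L || !is.finite(B0) || B0 <= 0) {
    abort_domain("`B0` must be a single positive, finite burden.")
  }
  if (!(horizon > 0)) abort_domain("`horizon` must be positive.")
  exp_law <- model$growth$law == "exponential"

  if (B0 >= model$omega_d) {
    return(list(outcome = "detectable_at_t0", t_R = 0,
                method = if (exp_law) "closed_form" else "ode_event"))
  }
  if (model$viability_term && B0 <= model$eps_V) {
    return(list(outcome = "cure", t_R = NA_real_,
                method = if (exp_law) "closed_form" else "ode_event"))
  }
  if (exp_law) {
    tR <- if (model$viability_term) {
      exponential_recurrence_time(B0, model$growth$lambda, model$eps_V,
                                  model$omega_d)
    } else {
      log(model$omega_d / B0) / model$growth$lambda
    }
    method <- "closed_form"
  } else {
    tR <- ode_recurrence_time(model, B0, K = K, horizon = horizon)
    method <- "ode_event"
  }
  if (is.na(tR) || tR > horizon) {
    list(outcome = "beyond_horizon", t_R = NA_real_, method = method)
  } else {
    list(outcome = "progression", t_R = tR, method = method)
  }
}

#' Simulate recurrence outcomes for a cohort
#'
#' Data-frame-first wrapper: takes a cohort tibble (from
#' [sample_cohort()] or built by hand with a `B0` column and optional
#' per-patient `K`) and appends each patient's outcome, recurrence time
#' and solution method.
#'
#' @param cohort A data frame with column `B0` (cc) and optionally `K`.
#' @param model A [regrowth_model()].
#' @param horizon Follow-up horizon in days.
#'
#' @return The input tibble with columns `outcome`, `t_R` (days, `NA`
#'   for cure/beyond-horizon) and `method` appended.
#' @export
#' @examples
#' m <- regrowth_model(growth_law("exponential", 0.0015), 0.01, 0.056)
#' sample_cohort(burden_dist("arithmetic", 0.05, 0.06), 10, seed = 1) |>
#'   simulate_recurrence(m)
simulate_recurrence <- function(cohort, model, horizon = 7300) {
  stopifnot(is.data.frame(cohort), "B0" %in% names(cohort))
  has_K <- "K" %in% names(cohort)
  if (model$growth$law != "exponential" && !has_K &&
      is.null(model$growth$K)) {
    abort_config("non-exponential laws need `K` in the model or the cohort.")
  }
  if (model$growth$law == "exponential") {
    # vectorised closed-form fast path
    tR <- if (model$viability_term) {
      exponential_recurrence_time(cohort$B0, model$growth$lambda,
                                  model$eps_V, model$omega_d)
    } else {
      pmax(log(model$omega_d / cohort$B0) / model$growth$lambda, 0)
    }
    cured <- model$viability_term & cohort$B0 <= model$eps_V
    outcome <- dplyr::case_when(
      cohort$B0 >= model$omega_d ~ "detectable_at_t0",
      cured ~ "cure",
      tR > horizon ~ "beyond_horizon",
      TRUE ~ "progression"
    )
    tR[outcome %in% c("cure", "beyond_horizon")] <- NA_real_
    res <- tibble::tibble(outcome = outcome, t_R = tR,
                          method = "closed_form")
  } else {
    res <- purrr::pmap(
      list(cohort$B0, if (has_K) cohort$K else list(NULL)),
      function(B0, K) {
        r <- patient_recurrence_time(B0, model, K = K, horizon = horizon)
        tibble::tibble(outcome = r$outcome, t_R = r$t_R, method = r$method)
      }) |> purrr::list_rbind()
  }
  dplyr::bind_cols(tibble::as_tibble(cohort), res)
}

#' Round recurrence times up to scheduled surveillance visits
#'
#' The simulator assumes continuous monitoring: recurrence is recorded
#' the instant the burden reaches the detection threshold. Real cohorts
#' are seen at scheduled visits, so an observed recurrence time is the
#' first visit at or after the true crossing. This helper applies such
#' a visit grid to simulated outcomes; crossings after the last visit
#' become `beyond_horizon`.
#'
#' @param outcomes A [simulate_recurrence()] result.
#' @param visit_times Scheduled visit times in days, strictly
#'   increasing, `>= 0`.
#'
#' @return The outcomes tibble with `t_R` rounded up to visit times and
#'   outcomes reclassified where the crossing falls after the last
#'   visit.
#' @export
apply_surveillance <- function(outcomes, visit_times) {
  stopifnot(is.data.frame(outcomes), "t_R" %in% names(outcomes))
  if (length(visit_times) < 1 || any(visit_times < 0) ||
      any(diff(visit_times) <= 0)) {
    abort_domain("`visit_times` must be nonnegative and strictly increasing.")
  }
  # first visit at or after the crossing: exact matches stay at their visit
  i <- findInterval(outcomes$t_R, visit_times)
  at_visit <- i >= 1L & !is.na(outcomes$t_R) &
    visit_times[pmax(i, 1L)] == outcomes$t_R
  idx <- ifelse(at_visit, i, i + 1L)
  seen <- !is.na(outcomes$t_R) & idx <= length(visit_times)
  out <- outcomes
  out$t_R[seen] <- visit_times[idx[seen]]
  missed <- !is.na(outcomes$t_R) & idx > length(visit_times)
  out$t_R[missed] <- NA_real_
  out$outcome[missed] <- "beyond_horizon"
  out
}
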