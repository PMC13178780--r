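# Growth laws and the threshold-modified regrowth dynamics.
#
# State variable is the viable tumor burden B (cc). The net dynamics are
#   dB/dt = f(B) * (B/eps_V - 1)
# where f is a classic growth law (exponential, logistic, Gompertz) and
# eps_V is the minimum viability threshold: burdens below it decay to zero
# (cure), burdens above it regrow until they cross the detection threshold
# omega_d (recurrence).

#' Growth-law parameter set
#'
#' Bundles a growth-law choice with its intrinsic rate and, for the
#' saturating laws, a carrying capacity.
#'
#' @param law One of `"exponential"`, `"logistic"`, `"gompertz"`.
#' @param lambda Intrinsic growth rate, per day; must be positive.
#' @param K Carrying capacity in cc; required (and positive) for the
#'   logistic and Gompertz laws, ignored for the exponential law.
#'
#' @return An object of class `growth_law`.
#' @export
#' @examples
#' growth_law("logistic", lambda = 0.0009, K = 13.8)
growth_law <- function(law = c("exponential", "logistic", "gompertz"),
                       lambda, K = NULL) {
  law <- match.arg(law)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    abort_config("`lambda` must be a single positive, finite number.")
  }
  if (law != "exponential") {
    if (is.null(K) || !is.numeric(K) || length(K) != 1L || !is.finite(K) ||
        K <= 0) {
      abort_config(sprintf("`K` must be a single positive number for the %s law.",
                           law))
    }
  } else {
    K <- NULL
  }
  structure(list(law = law, lambda = lambda, K = K), class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat("<growth_law> ", x$law, ": lambda = ", format(x$lambda), "/day",
      if (!is.null(x$K)) paste0(", K = ", format(x$K), " cc"), "\n", sep = "")
  invisible(x)
}

#' Intrinsic growth rate f(V)
#'
#' Evaluates the unmodified growth law: `lambda * V` (exponential),
#' `lambda * V * (1 - V/K)` (logistic) or `lambda * V * log(K/V)`
#' (Gompertz). `V = 0` returns exactly 0 for every law (the continuous
#' limit at the extinction fixed point). The Gompertz law is defined for
#' `V > K` too (negative rate); its log argument is floored at 1e-30 cc
#' to avoid overflow at vanishing volumes.
#'
#' @param params A [growth_law()] object.
#' @param V Volume in cc; vectorised, all values must be non-negative.
#' @param K Optional per-patient carrying capacity overriding `params$K`
#'   (recycled against `V`).
#'
#' @return Growth rate(s) in cc/day, same length as `V`.
#' @export
#' @examples
#' gl <- growth_law("logistic", lambda = 1, K = 13.8)
#' growth_rate(gl, 0.056) / (1 * 0.056) # ~0.996
growth_rate <- function(params, V, K = NULL) {
  stopifnot(inherits(params, "growth_law"))
  if (!is.numeric(V) || any(!is.finite(V))) {
    abort_domain("`V` must be finite and numeric.")
  }
  if (any(V < 0)) abort_domain("`V` must be non-negative.")
  K <- K %||% params$K
  lam <- params$lambda
  switch(params$law,
    exponential = lam * V,
    logistic = {
      if (is.null(K)) abort_config("logistic law requires `K`.")
      lam * V * (1 - V / K)
    },
    gompertz = {
      if (is.null(K)) abort_config("gompertz law requires `K`.")
      r <- lam * V * log(K / pmax(V, 1e-30))
      r[V == 0] <- 0
      r
    }
  )
}

#' Regrowth model
#'
#' The full per-patient model: a growth law plus the minimum viability
#' threshold `eps_V` (cc) below which the burden decays to zero, and the
#' detection threshold `omega_d` (cc) at which recurrence is declared.
#' With `viability_term = TRUE` the net dynamics are
#' `dB/dt = f(B) * (B/eps_V - 1)`; with `FALSE` they are plain `f(B)`
#' (the comparison variant in which every patient eventually recurs).
#'
#' @param growth A [growth_law()] object.
#' @param eps_V Minimum viable burden threshold, cc, `>= 0`. Must be 0
#'   only when `viability_term = FALSE`.
#' @param omega_d Detection threshold, cc, `> eps_V`; for the saturating
#'   laws also `< K` when the model carries a fixed `K`.
#' @param viability_term Logical; include the `(B/eps_V - 1)` factor.
#'
#' @return An object of class `regrowth_model`.
#' @export
#' @examples
#' regrowth_model(growth_law("exponential", 0.0015),
#'                eps_V = 0.01, omega_d = 0.056)
regrowth_model <- function(growth, eps_V, omega_d, viability_term = TRUE) {
  stopifnot(inherits(growth, "growth_law"))
  if (!is.numeric(eps_V) || length(eps_V) != 1L || !is.finite(eps_V) ||
      eps_V < 0) {
    abort_config("`eps_V` must be a single finite number >= 0.")
  }
  if (!is.numeric(omega_d) || length(omega_d) != 1L || !is.finite(omega_d) ||
      omega_d <= 0) {
    abort_config("`omega_d` must be a single positive number.")
  }
  if (eps_V >= omega_d) {
    abort_config(sprintf(
      "`eps_V` (%g) must be strictly below `omega_d` (%g).", eps_V, omega_d))
  }
  if (!is.null(growth$K) && omega_d >= growth$K) {
    abort_config(sprintf(
      "`omega_d` (%g) must be below the carrying capacity `K` (%g).",
      omega_d, growth$K))
  }
  if (isTRUE(viability_term) && eps_V == 0) {
    abort_config(paste0(
      "`eps_V` = 0 makes the viability factor (B/eps_V - 1) undefined; ",
      "set `viability_term = FALSE` for threshold-free dynamics instead."))
  }
  structure(list(growth = growth, eps_V = eps_V, omega_d = omega_d,
                 viability_term = isTRUE(viability_term)),
            class = "regrowth_model")
}

#' @export
print.regrowth_model <- function(x, ...) {
  cat("<regrowth_model> law = ", x$growth$law,
      ", lambda = ", format(x$growth$lambda), "/day",
      if (!is.null(x$growth$K)) paste0(", K = ", format(x$growth$K), " cc"),
      "\n  eps_V = ", format(x$eps_V), " cc, omega_d = ",
      format(x$omega_d), " cc, viability term ",
      if (x$viability_term) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Net burden change dB/dt
#'
#' With the viability term on, returns `f(B) * (B/eps_V - 1)`: negative
#' for `0 < B < eps_V`, zero at `B = 0` and `B = eps_V`, positive above.
#' With the term off, returns plain `f(B)`.
#'
#' @param model A [regrowth_model()].
#' @param B Viable burden in cc; vectorised, non-negative.
#' @param K Optional per-patient carrying capacity override.
#'
#' @return Net rate(s) in cc/day.
#' @export
net_rate <- function(model, B, K = NULL) {
  stopifnot(inherits(model, "regrowth_model"))
  f <- growth_rate(model$growth, B, K = K)
  if (!model$viability_term) return(f)
  f * (B / model$eps_V - 1)
}

# Blow-up time of the exponential-law dynamics above eps_V:
# denominator of the closed form hits zero at
# t* = (1/lambda) * log((1/eps_V) / (1/eps_V - 1/B0)).
exp_blowup_time <- function(B0, lambda, eps_V) {
  ifelse(B0 > eps_V,
         (1 / lambda) * log((1 / eps_V) / (1 / eps_V - 1 / B0)),
         Inf)
}

#' Closed-form exponential-law burden trajectory
#'
#' The net dynamics with the exponential law,
#' `dB/dt = lambda * B * (B/eps_V - 1)`, form a Bernoulli equation with
#' exact solution `B(t) = 1 / (1/eps_V + (1/B0 - 1/eps_V) * exp(lambda t))`.
#' For `B0 > eps_V` the solution blows up in finite time
#' `t* = (1/lambda) log((1/eps_V)/(1/eps_V - 1/B0))`; evaluation at or
#' beyond `t*` is a domain error naming that time.
#'
#' @param B0 Initial burden, cc, `> 0`.
#' @param lambda Growth rate, per day.
#' @param eps_V Viability threshold, cc, `> 0`.
#' @param t Time(s) from end of treatment, days, `>= 0`; vectorised.
#'
#' @return Burden(s) in cc at `t`.
#' @export
#' @examples
#' exponential_burden_at(0.02, 0.0015, 0.01, 331) # ~0.056
exponential_burden_at <- function(B0, lambda, eps_V, t) {
  if (!is.numeric(B0) || length(B0) != 1L || !is.finite(B0) || B0 <= 0) {
    abort_domain("`B0` must be a single positive, finite burden.")
  }
  stopifnot(is.numeric(lambda), lambda > 0, is.numeric(eps_V), eps_V > 0)
  if (any(!is.finite(t)) || any(t < 0)) {
    abort_domain("`t` must be finite and non-negative.")
  }
  denom <- 1 / eps_V + (1 / B0 - 1 / eps_V) * exp(lambda * t)
  if (any(denom <= 0)) {
    abort_domain(sprintf(
      "burden diverges at t* = %.6g days; requested times reach or exceed it.",
      exp_blowup_time(B0, lambda, eps_V)))
  }
  1 / denom
}

#' Closed-form exponential-law recurrence time
#'
#' First time the exponential-law trajectory reaches the detection
#' threshold: `t_R = (1/lambda) log[(1/eps_V - 1/omega_d) /
#' (1/eps_V - 1/B0)]`. Returns 0 for burdens already detectable
#' (`B0 >= omega_d`) and `NA` (cure) for `B0 <= eps_V`. Vectorised over
#' `B0`.
#'
#' @param B0 Initial burden(s), cc, `> 0`.
#' @param lambda Growth rate, per day.
#' @param eps_V Viability threshold, cc, with `0 < eps_V < omega_d`.
#' @param omega_d Detection threshold, cc.
#'
#' @return Recurrence time(s) in days, `NA` for cured patients.
#' @export
#' @examples
#' exponential_recurrence_time(0.02, 0.0015, 0.01, 0.056) # ~331 days
exponential_recurrence_time <- function(B0, lambda, eps_V, omega_d) {
  stopifnot(is.numeric(lambda), lambda > 0)
  if (!(eps_V > 0 && eps_V < omega_d)) {
    abort_domain("requires 0 < eps_V < omega_d.")
  }
  if (!is.numeric(B0) || any(!is.finite(B0)) || any(B0 <= 0)) {
    abort_domain("`B0` must be positive and finite.")
  }
  tR <- rep(NA_real_, length(B0))
  tR[B0 >= omega_d] <- 0
  grow <- B0 > eps_V & B0 < omega_d
  tR[grow] <- (1 / lambda) *
    log((1 / eps_V - 1 / omega_d) / (1 / eps_V - 1 / B0[grow]))
  tR
}

# deSolve derivative closure for one patient.
ode_deriv <- function(model, K) {
  force(model); force(K)
  function(t, y, parms) {
    B <- max(y[[1]], 0)
    list(net_rate(model, B, K = K))
  }
}

#' Simulate a burden trajectory
#'
#' Integrates the net dynamics from `B0` over a time grid with an
#' adaptive solver (deSolve `lsodar`, rtol 1e-10, atol 1e-14). For
#' burdens above `eps_V` the exponential-law dynamics diverge in finite
#' time; integration stops at a blow-up ceiling (default `1e4` cc for
#' the exponential law, `10 * K` otherwise) and the returned trajectory
#' is truncated with `attr(., "truncated") = TRUE`.
#'
#' @param model A [regrowth_model()].
#' @param B0 Initial burden, cc, `> 0`.
#' @param t_grid Output times in days, starting at 0, strictly increasing.
#' @param K Optional per-patient carrying capacity.
#' @param ceiling Blow-up ceiling in cc.
#'
#' @return A tibble with columns `time` (days) and `burden` (cc), class
#'   `regrowth_trajectory`, with attribute `truncated`.
#' @export
#' @examples
#' m <- regrowth_model(growth_law("exponential", 0.0015), 0.01, 0.056)
#' simulate_trajectory(m, 0.02, seq(0, 400, by = 50))
simulate_trajectory <- function(model, B0, t_grid, K = NULL, ceiling = NULL) {
  stopifnot(inherits(model, "regrowth_model"))
  if (!is.numeric(B0) || length(B0) != 1L || !is.finite(B0) || B0 <= 0) {
    abort_domain("`B0` must be a single positive, finite burden.")
  }
  if (length(t_grid) < 2L || t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    abort_domain("`t_grid` must start at 0 and be strictly increasing.")
  }
  Kp <- K %||% model$growth$K
  ceiling <- ceiling %||% if (is.null(Kp)) 1e4 else 10 * Kp
  sol <- tryCatch(
    deSolve::ode(y = c(B = B0), times = t_grid, func = ode_deriv(model, K),
                 parms = NULL, method = "lsodar",
                 rtol = 1e-10, atol = 1e-14,
                 rootfunc = function(t, y, parms) y[[1]] - ceiling),
    error = function(e) {
      rlang::abort(paste0("burden integration failed: ", conditionMessage(e)),
                   class = "regrowr_integration_error")
    })
  truncated <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  out <- tibble::tibble(time = sol[, "time"], burden = pmax(sol[, "B"], 0))
  structure(out, truncated = truncated,
            class = c("regrowth_trajectory", class(out)))
}
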