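# Calibration of (lambda, omega_d, eps_V) to observed event-free curves.
#
# The loss is unweighted least squares on event-free fractions at the
# observed time points, summed across arms that share global parameters.
# Candidate parameters are evaluated on replicate-mean simulated curves
# built from burdens drawn ONCE per fit (common random numbers): with the
# burden distributions fixed, the loss surface is then exactly
# deterministic, so the derivative-free simplex search is reproducible.
# The exponential growth law admits a closed-form recurrence time, which
# keeps each loss evaluation a handful of vectorised operations.

#' Squared-error loss between a simulated and an observed curve
#'
#' Sum over observed time points of squared differences between the
#' simulated event-free fraction (linearly interpolated to the observed
#' times) and the observed one.
#'
#' @param simulated A data frame with `time` and `survival` columns (a
#'   [cohort_curve()] result or a replicate mean); its grid must span
#'   the observed times.
#' @param observed A data frame with `time_days` and
#'   `event_free_fraction` columns (see [read_observed_curve()]).
#'
#' @return A non-negative scalar.
#' @export
curve_loss <- function(simulated, observed) {
  stopifnot(is.data.frame(simulated),
            all(c("time", "survival") %in% names(simulated)),
            is.data.frame(observed),
            all(c("time_days", "event_free_fraction") %in% names(observed)))
  if (max(observed$time_days) > max(simulated$time)) {
    abort_domain(sprintf(
      "observed time %g d exceeds the simulation horizon %g d.",
      max(observed$time_days), max(simulated$time)))
  }
  sim <- approx(simulated$time, simulated$survival,
                xout = observed$time_days)$y
  sum((sim - observed$event_free_fraction)^2)
}

# Vectorised exponential-law recurrence times over a burden matrix.
exp_tR_matrix <- function(B, lambda, eps_V, omega_d) {
  tR <- matrix(NA_real_, nrow(B), ncol(B))
  tR[B >= omega_d] <- 0
  g <- B > eps_V & B < omega_d
  tR[g] <- (1 / lambda) *
    log((1 / eps_V - 1 / omega_d) / (1 / eps_V - 1 / B[g]))
  tR
}

# Replicate-mean event-free fraction at given times from a recurrence-time
# matrix (patients x replicates); NA = never recurs.
mean_survival_at <- function(tR, times) {
  vapply(times, function(t) mean(is.na(tR) | tR > t), numeric(1))
}

#' Fit regrowth parameters to observed event-free curves
#'
#' Derivative-free (Nelder-Mead) minimisation of [curve_loss()] summed
#' across arms, over a log/logit reparameterisation that enforces
#' `0 < eps_V < omega_d` by construction: `lambda = exp(a)`,
#' `omega_d = exp(b)`, `eps_V = omega_d * plogis(c)`. Each candidate is
#' scored on replicate-mean curves from `n_reps` cohorts of `n` patients
#' per arm, drawn once at the start (common random numbers). The burden
#' distributions are fixed inputs; the exponential growth law is used
#' (its closed-form recurrence time makes the replicate-mean loss exact
#' and fast).
#'
#' @param observed A data frame with `time_days` and
#'   `event_free_fraction`, or a list of such data frames (one per arm).
#' @param dists A [burden_dist()] or list of them, matching `observed`.
#' @param init Named numeric vector `c(lambda=, omega_d=, eps_V=)` of
#'   starting values satisfying `0 < eps_V < omega_d`.
#' @param n Patients per arm per replicate.
#' @param n_reps Replicates per candidate evaluation.
#' @param seed Integer seed for the (single) burden draw.
#' @param maxit Nelder-Mead iteration budget.
#' @param reltol Relative convergence tolerance on the loss.
#'
#' @return An object of class `regrowth_fit`: fitted parameters, loss,
#'   convergence diagnostics, and the replicate-mean fitted curve per
#'   arm at the optimum. Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' obs <- tibble::tibble(time_days = c(0, 365, 1825, 7300),
#'                       event_free_fraction = c(0.95, 0.6, 0.3, 0.25))
#' d <- burden_dist("log_space", -8, 6.8)
#' fit_parameters(obs, d, c(lambda = 0.004, omega_d = 0.5, eps_V = 1e-4),
#'                n = 100, n_reps = 10, seed = 1, maxit = 50)
fit_parameters <- function(observed, dists, init, n = 265, n_reps = 100,
                           seed = 1L, maxit = 500, reltol = 1e-6) {
  if (is.data.frame(observed)) observed <- list(observed)
  if (inherits(dists, "burden_dist")) dists <- list(dists)
  if (length(observed) != length(dists)) {
    abort_config("`observed` and `dists` must have one entry per arm.")
  }
  purrr::walk(observed, validate_observed_curve)
  if (!all(c("lambda", "omega_d", "eps_V") %in% names(init))) {
    abort_config("`init` must name lambda, omega_d and eps_V.")
  }
  if (!(init[["eps_V"]] > 0 && init[["eps_V"]] < init[["omega_d"]] &&
        init[["lambda"]] > 0)) {
    abort_config("`init` must satisfy 0 < eps_V < omega_d and lambda > 0.")
  }

  # common random numbers: one burden matrix per arm, fixed for the fit
  draws <- with_seed(seed, purrr::map(dists, function(d) {
    matrix(rlnorm(n * n_reps, d$meanlog, d$sdlog), nrow = n)
  }))
  horizon <- max(purrr::map_dbl(observed, ~ max(.x$time_days)))
  grid <- unique(sort(c(0, unlist(purrr::map(observed, "time_days")))))

  unpack <- function(par) {
    omega_d <- exp(par[2])
    list(lambda = exp(par[1]), omega_d = omega_d,
         eps_V = omega_d * stats::plogis(par[3]))
  }
  objective <- function(par) {
    p <- unpack(par)
    sum(purrr::map2_dbl(draws, observed, function(B, obs) {
      tR <- exp_tR_matrix(B, p$lambda, p$eps_V, p$omega_d)
      sim <- mean_survival_at(tR, obs$time_days)
      sum((sim - obs$event_free_fraction)^2)
    }))
  }
  par0 <- c(log(init[["lambda"]]), log(init[["omega_d"]]),
            stats::qlogis(init[["eps_V"]] / init[["omega_d"]]))
  opt <- optim(par0, objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  p <- unpack(opt$par)

  fitted_curves <- purrr::imap(observed, function(obs, i) {
    tR <- exp_tR_matrix(draws[[i]], p$lambda, p$eps_V, p$omega_d)
    tibble::tibble(arm = i, time = grid,
                   survival = mean_survival_at(tR, grid))
  }) |> purrr::list_rbind()

  structure(list(
    estimates = tibble::tibble(
      term = c("lambda", "omega_d", "eps_V"),
      estimate = c(p$lambda, p$omega_d, p$eps_V),
      unit = c("1/day", "cc", "cc")),
    loss = opt$value,
    converged = opt$convergence == 0L,
    iterations = opt$counts[["function"]],
    fitted_curves = fitted_curves,
    observed = observed,
    settings = list(n = n, n_reps = n_reps, seed = seed, maxit = maxit,
                    reltol = reltol, init = init, horizon = horizon)
  ), class = "regrowth_fit")
}

#' @export
print.regrowth_fit <- function(x, ...) {
  cat("<regrowth_fit> ", if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " evaluations; loss = ",
      format(x$loss, digits = 5), "\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' @describeIn fit_parameters Tidy the fitted parameters (one row per term).
#' @param x A `regrowth_fit` object.
#' @param ... Unused.
#' @method tidy regrowth_fit
#' @export
tidy.regrowth_fit <- function(x, ...) {
  x$estimates
}

#' @describeIn fit_parameters One-row fit summary (loss, convergence,
#'   evaluation count, replicate settings).
#' @method glance regrowth_fit
#' @export
glance.regrowth_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, converged = x$converged,
                 iterations = x$iterations,
                 n_arms = length(x$observed),
                 n = x$settings$n, n_reps = x$settings$n_reps)
}
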