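# Cohort-level recurrence curves and their features.
#
# The cohort recurrence fraction is the exact average of the per-patient
# step indicators, R(t) = (1/n) * sum_i R_i(t); the event-free
# (Kaplan-Meier-style) curve is 1 - R(t). Curves are evaluated on a
# uniform grid from exact event times, not binned histograms.

default_grid <- function(horizon = 7300, step = 1) seq(0, horizon, by = step)

#' Cohort recurrence curve
#'
#' Averages per-patient recurrence indicators over a time grid. Cured
#' and beyond-horizon patients contribute 0 at every grid time.
#'
#' @param outcomes A data frame with a `t_R` column (days, `NA` for
#'   non-recurrent patients), as returned by [simulate_recurrence()].
#' @param t_grid Evaluation times in days, strictly increasing from 0.
#'
#' @return A tibble of class `recurrence_curve` with columns `time`,
#'   `recurrence` (nondecreasing, in `[0, 1]`) and `survival`
#'   (`1 - recurrence`); attribute `n_patients`.
#' @export
#' @examples
#' cohort_curve(tibble::tibble(t_R = c(100, NA)), t_grid = c(0, 99, 100, 200))
cohort_curve <- function(outcomes, t_grid = default_grid()) {
  stopifnot(is.data.frame(outcomes), "t_R" %in% names(outcomes))
  n <- nrow(outcomes)
  if (n == 0L) abort_domain("empty cohort.")
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    abort_domain("`t_grid` must start at 0 and be strictly increasing.")
  }
  events <- sort(outcomes$t_R[!is.na(outcomes$t_R)])
  # findInterval counts events with t_R <= t: inclusive, right-continuous
  R <- findInterval(t_grid, events) / n
  out <- tibble::tibble(time = t_grid, recurrence = R, survival = 1 - R)
  structure(out, n_patients = n,
            class = c("recurrence_curve", class(out)))
}

#' Summary features of a recurrence curve
#'
#' The three curve features the model parameters control: the
#' y-intercept (event-free fraction at `t = 0`, governed by the
#' detection threshold), the plateau (the cure-fraction asymptote, read
#' at the final grid time, governed by the viability threshold), and a
#' drop-rate proxy (time until the curve first comes within `tol` of
#' its plateau, governed by the regrowth rate).
#'
#' @param curve A [cohort_curve()] result.
#' @param tol Closeness tolerance for the drop-rate proxy (event-free
#'   fraction units).
#'
#' @return A one-row tibble with `y_intercept`, `plateau`,
#'   `drop_rate_proxy` (days).
#' @export
curve_features <- function(curve, tol = 0.01) {
  stopifnot(is.data.frame(curve),
            all(c("time", "survival") %in% names(curve)))
  s <- curve$survival
  plateau <- s[length(s)]
  tibble::tibble(
    y_intercept = s[1],
    plateau = plateau,
    drop_rate_proxy = curve$time[which(s <= plateau + tol)[1]]
  )
}

# first time the event-free fraction falls to 0.5 or below (NA if never)
median_event_free_time <- function(curve) {
  i <- which(curve$survival <= 0.5)[1]
  if (is.na(i)) NA_real_ else curve$time[i]
}

with_param <- function(model, param, value) {
  g <- model$growth
  switch(param,
    lambda = regrowth_model(growth_law(g$law, value, g$K),
                            model$eps_V, model$omega_d, model$viability_term),
    eps_V = regrowth_model(g, value, model$omega_d, model$viability_term),
    omega_d = regrowth_model(g, model$eps_V, value, model$viability_term)
  )
}

#' Sweep one model parameter over a cohort
#'
#' Re-runs the same sampled cohort (common random numbers: one seed, one
#' draw, reused at every sweep point) across a grid of values of
#' `eps_V`, `omega_d` or `lambda`, so curve differences are
#' parameter-driven only.
#'
#' @param dist A [burden_dist()] for the cohort.
#' @param model Baseline [regrowth_model()].
#' @param param One of `"eps_V"`, `"omega_d"`, `"lambda"`.
#' @param values Numeric sweep values; each point must satisfy the model
#'   constraints (`eps_V < omega_d` throughout).
#' @param n Cohort size.
#' @param seed Integer seed for the (single) cohort draw.
#' @param t_grid Curve evaluation grid.
#' @param horizon Follow-up horizon in days.
#'
#' @return A tibble of class `parameter_sweep`, one row per sweep value:
#'   `param`, `value`, the three [curve_features()] columns, and a
#'   `curve` list-column of `recurrence_curve` tibbles.
#' @export
parameter_sweep <- function(dist, model, param = c("eps_V", "omega_d", "lambda"),
                            values, n, seed,
                            t_grid = default_grid(), horizon = max(t_grid)) {
  param <- match.arg(param)
  cohort <- sample_cohort(dist, n, seed)
  rows <- purrr::map(values, function(v) {
    m_v <- tryCatch(with_param(model, param, v), error = function(e) {
      abort_config(sprintf("sweep point %s = %g is invalid: %s",
                           param, v, conditionMessage(e)))
    })
    curve <- cohort_curve(simulate_recurrence(cohort, m_v, horizon = horizon),
                          t_grid)
    dplyr::bind_cols(tibble::tibble(param = param, value = v),
                     curve_features(curve),
                     tibble::tibble(curve = list(curve)))
  })
  out <- purrr::list_rbind(rows)
  structure(out, class = c("parameter_sweep", class(out)))
}

#' Compare two trial arms
#'
#' Simulates both arms on a shared grid under common random numbers (the
#' same seed drives both arms' draws, so identical specifications give
#' identical curves) and reports feature differences.
#'
#' @param arm1,arm2 Lists with elements `dist` (a [burden_dist()]),
#'   `model` (a [regrowth_model()]), `n` (cohort size) and optionally
#'   `label` and `K_dist`.
#' @param seed Integer seed, shared by both arms.
#' @param t_grid Curve evaluation grid.
#' @param horizon Follow-up horizon in days.
#'
#' @return An object of class `arm_comparison`: a list with `curves`
#'   (long tibble: `arm`, `time`, `recurrence`, `survival`) and `deltas`
#'   (one row per feature, arm1 minus arm2).
#' @export
compare_arms <- function(arm1, arm2, seed,
                         t_grid = default_grid(), horizon = max(t_grid)) {
  arms <- list(arm1, arm2)
  labels <- purrr::imap_chr(arms, function(a, i) a$label %||% paste0("arm", i))
  curves <- purrr::map(arms, function(a) {
    cohort <- sample_cohort(a$dist, a$n, seed, K_dist = a$K_dist)
    cohort_curve(simulate_recurrence(cohort, a$model, horizon = horizon),
                 t_grid)
  })
  feats <- purrr::map(curves, curve_features)
  deltas <- tibble::tibble(
    feature = c("y_intercept", "plateau", "median_event_free_time"),
    arm1 = c(feats[[1]]$y_intercept, feats[[1]]$plateau,
             median_event_free_time(curves[[1]])),
    arm2 = c(feats[[2]]$y_intercept, feats[[2]]$plateau,
             median_event_free_time(curves[[2]]))
  )
  deltas$delta <- deltas$arm1 - deltas$arm2
  long <- purrr::map2(labels, curves, function(lab, cv) {
    dplyr::mutate(tibble::as_tibble(cv), arm = lab, .before = 1)
  }) |> purrr::list_rbind()
  structure(list(curves = long, deltas = deltas, labels = labels),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat("<arm_comparison> arms:", paste(x$labels, collapse = " vs "), "\n")
  print(x$deltas)
  invisible(x)
}

#' Replicate confidence band for a recurrence curve
#'
#' Simulates `n_reps` independent cohorts from the same specification
#' and returns the pointwise mean event-free curve with 2.5/97.5
#' percentile envelopes (empirical quantiles with linear interpolation,
#' Weibull plotting positions; at `n_reps = 2` this degenerates to
#' min/max).
#'
#' @param dist A [burden_dist()].
#' @param model A [regrowth_model()].
#' @param n Cohort size per replicate.
#' @param n_reps Number of replicates, `>= 2`.
#' @param seed Integer seed; replicate draws are consecutive blocks of
#'   one stream, so the band is reproducible.
#' @param K_dist Optional carrying-capacity distribution.
#' @param t_grid Curve evaluation grid.
#' @param horizon Follow-up horizon in days.
#'
#' @return A tibble of class `replicate_band` with columns `time`,
#'   `mean`, `lower95`, `upper95`; attribute `n_reps`.
#' @export
replicate_band <- function(dist, model, n, n_reps, seed, K_dist = NULL,
                           t_grid = default_grid(), horizon = max(t_grid)) {
  if (!(n_reps >= 2)) abort_config("`n_reps` must be >= 2.")
  draws <- with_seed(seed, {
    B <- matrix(rlnorm(n * n_reps, dist$meanlog, dist$sdlog), nrow = n)
    K <- if (!is.null(K_dist)) {
      matrix(rlnorm(n * n_reps, K_dist$meanlog, K_dist$sdlog), nrow = n)
    }
    list(B = B, K = K)
  })
  surv <- vapply(seq_len(n_reps), function(r) {
    cohort <- tibble::tibble(patient = seq_len(n), B0 = draws$B[, r])
    if (!is.null(draws$K)) cohort$K <- draws$K[, r]
    cohort_curve(simulate_recurrence(cohort, model, horizon = horizon),
                 t_grid)$survival
  }, numeric(length(t_grid)))
  out <- tibble::tibble(
    time = t_grid,
    mean = rowMeans(surv),
    lower95 = apply(surv, 1, quantile, probs = 0.025, names = FALSE,
                    type = 6),
    upper95 = apply(surv, 1, quantile, probs = 0.975, names = FALSE,
                    type = 6)
  )
  structure(out, n_reps = n_reps,
            class = c("replicate_band", class(out)))
}
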