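# Scenario configuration, CSV I/O and the fixture generator.
#
# A scenario is a named parameter set (burden distribution(s), growth law,
# thresholds, cohort size, seed, horizon, grid step). Built-in scenarios
# carry the demonstration parameter sets; user scenarios load from a YAML
# file with the same structure. Unknown keys are rejected, not ignored.

scenario_keys <- c("name", "dist", "arms", "law", "lambda", "K", "K_dist",
                   "eps_V", "omega_d", "viability_term", "n_patients", "n_reps",
                   "seed", "horizon", "grid_step")
dist_keys <- c("family", "convention", "param1", "param2", "label")

builtin_scenario_list <- function() {
  list(
    workflow_demo = list(
      name = "workflow_demo",
      dist = list(family = "lognormal", convention = "arithmetic",
                  param1 = 0.05, param2 = 0.06),
      law = "exponential", lambda = 0.0008,
      eps_V = 0.01, omega_d = 0.056,
      n_patients = 50, n_reps = 1, seed = 1, horizon = 7300, grid_step = 1
    ),
    baseline = list(
      name = "baseline",
      dist = list(family = "lognormal", convention = "arithmetic",
                  param1 = 0.05, param2 = 0.06),
      law = "exponential", lambda = 0.0015,
      eps_V = 0.01, omega_d = 0.056,
      n_patients = 1000, n_reps = 1, seed = 1, horizon = 7300, grid_step = 1
    ),
    trial_arms = list(
      name = "trial_arms",
      # the arm scale parameter is a free choice (not fixed by the source
      # parameter sets); equal scales preserve the arm ordering
      arms = list(
        list(family = "lognormal", convention = "mean_logsd",
             param1 = 0.03, param2 = 1.0, label = "arm1"),
        list(family = "lognormal", convention = "mean_logsd",
             param1 = 0.05, param2 = 1.0, label = "arm2")
      ),
      law = "exponential", lambda = 0.0015,
      eps_V = 0.01, omega_d = 0.056,
      n_patients = 200, n_reps = 1, seed = 1, horizon = 7300, grid_step = 1
    ),
    growth_laws = list(
      name = "growth_laws",
      dist = list(family = "lognormal", convention = "mean_logsd",
                  param1 = 0.02, param2 = 0.5),
      K_dist = list(family = "lognormal", convention = "mean_logsd",
                    param1 = 13.8, param2 = 0.5),
      law = "exponential", lambda = 0.0009,
      eps_V = 0.015, omega_d = 0.056,
      n_patients = 50, n_reps = 1, seed = 1, horizon = 7300, grid_step = 1
    ),
    rtog9003_like = list(
      name = "rtog9003_like",
      arms = list(
        list(family = "lognormal", convention = "log_space",
             param1 = -8.0, param2 = 6.8, label = "standard"),
        list(family = "lognormal", convention = "log_space",
             param1 = -10.0, param2 = 7.6, label = "hyperfractionation")
      ),
      law = "exponential", lambda = 0.005,
      eps_V = 2.5e-4, omega_d = 0.4,
      n_patients = 265, n_reps = 100, seed = 1, horizon = 7300, grid_step = 1
    )
  )
}

#' Names of the built-in scenarios
#' @return A character vector.
#' @export
builtin_scenarios <- function() names(builtin_scenario_list())

parse_dist_block <- function(block, path) {
  unknown <- setdiff(names(block), dist_keys)
  if (length(unknown) > 0) {
    abort_config(sprintf("unknown key(s) %s under '%s'.",
                         paste0("'", unknown, "'", collapse = ", "), path))
  }
  missing <- setdiff(c("family", "convention", "param1", "param2"),
                     names(block))
  if (length(missing) > 0) {
    abort_config(sprintf("missing key(s) %s under '%s'.",
                         paste(missing, collapse = ", "), path))
  }
  if (!identical(block$family, "lognormal")) {
    abort_config(sprintf("'%s.family' must be 'lognormal'.", path))
  }
  d <- burden_dist(block$convention, block$param1, block$param2)
  attr(d, "label") <- block$label %||% NULL
  d
}

validate_scenario <- function(cfg) {
  unknown <- setdiff(names(cfg), scenario_keys)
  if (length(unknown) > 0) {
    abort_config(sprintf("unknown scenario key(s): %s.",
                         paste0("'", unknown, "'", collapse = ", ")))
  }
  for (key in c("law", "lambda", "eps_V", "omega_d", "n_patients", "seed")) {
    if (is.null(cfg[[key]])) {
      abort_config(sprintf("scenario key '%s' is required.", key))
    }
  }
  if (is.null(cfg$dist) && is.null(cfg$arms)) {
    abort_config("scenario needs either 'dist' or 'arms'.")
  }
  if (cfg$eps_V >= cfg$omega_d) {
    abort_config(sprintf(
      "'eps_V' (%g) must be strictly below 'omega_d' (%g).",
      cfg$eps_V, cfg$omega_d))
  }
  dists <- if (!is.null(cfg$arms)) {
    purrr::imap(cfg$arms, function(a, i) {
      parse_dist_block(a, paste0("arms[", i, "]"))
    })
  } else {
    list(parse_dist_block(cfg$dist, "dist"))
  }
  K_dist <- if (!is.null(cfg$K_dist)) parse_dist_block(cfg$K_dist, "K_dist")
  gl <- growth_law(cfg$law, cfg$lambda, K = cfg$K)
  model <- regrowth_model(gl, cfg$eps_V, cfg$omega_d,
                          viability_term = cfg$viability_term %||% TRUE)
  structure(list(
    name = cfg$name %||% "user_scenario",
    dists = dists, K_dist = K_dist, model = model,
    n = cfg$n_patients, n_reps = cfg$n_reps %||% 1L, seed = cfg$seed,
    horizon = cfg$horizon %||% 7300, grid_step = cfg$grid_step %||% 1
  ), class = "scenario")
}

#' Load a scenario by built-in name or YAML path
#'
#' Validates every constraint at load time (`eps_V < omega_d`, positive
#' rates, known keys only) and reports the offending key on failure.
#'
#' @param x A built-in scenario name (see [builtin_scenarios()]) or the
#'   path to a YAML scenario file with the same structure.
#'
#' @return An object of class `scenario`: validated distributions, a
#'   [regrowth_model()], cohort size, replicate count, seed, horizon and
#'   grid step.
#' @export
#' @examples
#' load_scenario("baseline")
load_scenario <- function(x) {
  builtins <- builtin_scenario_list()
  cfg <- if (x %in% names(builtins)) {
    builtins[[x]]
  } else if (file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    abort_config(sprintf(
      "'%s' is neither a built-in scenario (%s) nor an existing file.",
      x, paste(builtin_scenarios(), collapse = ", ")))
  }
  validate_scenario(cfg)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, ": ", length(x$dists), " arm(s), n = ", x$n,
      ", n_reps = ", x$n_reps, ", seed = ", x$seed, "\n", sep = "")
  print(x$model)
  invisible(x)
}

scenario_grid <- function(sc) default_grid(sc$horizon, sc$grid_step)

#' Run a scenario end to end
#'
#' Samples each arm's cohort, simulates recurrence and builds the
#' event-free curve(s) — the whole burden-distribution-to-curve
#' pipeline in one call.
#'
#' @param scenario A [load_scenario()] result or built-in name.
#'
#' @return A list with `cohorts` (tibble with `arm` column), `curves`
#'   (long tibble) and the validated `scenario`.
#' @export
#' @examples
#' run_scenario("workflow_demo")$curves
run_scenario <- function(scenario) {
  sc <- if (inherits(scenario, "scenario")) scenario else
    load_scenario(scenario)
  grid <- scenario_grid(sc)
  pieces <- purrr::imap(sc$dists, function(d, i) {
    lab <- attr(d, "label") %||% paste0("arm", i)
    cohort <- sample_cohort(d, sc$n, sc$seed + (i - 1L), K_dist = sc$K_dist)
    out <- simulate_recurrence(cohort, sc$model, horizon = sc$horizon)
    curve <- cohort_curve(out, grid)
    list(cohort = dplyr::mutate(out, arm = lab, .before = 1),
         curve = dplyr::mutate(tibble::as_tibble(curve), arm = lab,
                               .before = 1))
  })
  list(cohorts = purrr::list_rbind(purrr::map(pieces, "cohort")),
       curves = purrr::list_rbind(purrr::map(pieces, "curve")),
       scenario = sc)
}

#' Write a recurrence curve (or band) to CSV
#'
#' Columns `time_days`, `survival`, `recurrence_fraction`, plus
#' `lower95`, `upper95`, `n_reps` for replicate bands. UTF-8, `.`
#' decimal separator, header row.
#'
#' @param curve A `recurrence_curve` or `replicate_band` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  out <- if (inherits(curve, "replicate_band")) {
    tibble::tibble(time_days = curve$time, survival = curve$mean,
                   recurrence_fraction = 1 - curve$mean,
                   lower95 = curve$lower95, upper95 = curve$upper95,
                   n_reps = attr(curve, "n_reps"))
  } else {
    tibble::tibble(time_days = curve$time, survival = curve$survival,
                   recurrence_fraction = curve$recurrence)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_observed_curve <- function(df) {
  if (nrow(df) < 3) {
    abort_domain("an observed curve needs at least 3 points.")
  }
  if (any(df$time_days < 0) || any(diff(df$time_days) <= 0)) {
    bad <- which(c(FALSE, diff(df$time_days) <= 0) | df$time_days < 0)[1]
    abort_domain(sprintf("row %d: times must be >= 0 and strictly increasing.",
                         bad))
  }
  if (any(df$event_free_fraction < 0 | df$event_free_fraction > 1)) {
    bad <- which(df$event_free_fraction < 0 | df$event_free_fraction > 1)[1]
    abort_domain(sprintf("row %d: event-free fraction outside [0, 1].", bad))
  }
  inc <- which(diff(df$event_free_fraction) > 0)
  if (length(inc) > 0) {
    abort_domain(sprintf(
      "row %d: event-free fraction increases; observed curves must be nonincreasing.",
      inc[1] + 1L))
  }
  invisible(df)
}

#' Read an observed event-free curve from CSV
#'
#' Expects columns `time_days` and `event_free_fraction`; rejects empty
#' files, non-monotone times and increasing event-free fractions with a
#' row-numbered error. Round-trips with [write_curve()] output (the
#' `survival` column is accepted as an alias).
#'
#' @param path CSV file path.
#' @param label Optional arm label (defaults to the file name).
#' @return A tibble with `time_days`, `event_free_fraction` and
#'   attribute `label`.
#' @export
read_observed_curve <- function(path, label = NULL) {
  if (!file.exists(path)) abort_domain(sprintf("no such file: %s", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_domain(paste0("cannot parse ", path, ": ",
                                            conditionMessage(e))))
  if (nrow(df) == 0 || ncol(df) == 0) {
    abort_domain(sprintf("%s parses to an empty table.", path))
  }
  if (!"event_free_fraction" %in% names(df) && "survival" %in% names(df)) {
    df$event_free_fraction <- df$survival
  }
  if (!all(c("time_days", "event_free_fraction") %in% names(df))) {
    abort_domain(sprintf(
      "%s must have columns time_days and event_free_fraction.", path))
  }
  df <- tibble::as_tibble(df)[, c("time_days", "event_free_fraction")]
  validate_observed_curve(df)
  attr(df, "label") <- label %||% sub("\\.[^.]*$", "", basename(path))
  df
}

#' Generate plain-text fixtures for a scenario
#'
#' Runs a scenario and writes, per arm, a cohort CSV (`patient`, `B0`,
#' `outcome`, `t_R_days`), a curve CSV, and one `metadata.yaml`
#' recording every generating parameter and the seed. Outputs are
#' deterministic: the same scenario and seed give byte-identical files.
#'
#' @param scenario Built-in name or [load_scenario()] result.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional seed overriding the scenario's own.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixture <- function(scenario, out_dir, seed = NULL) {
  sc <- if (inherits(scenario, "scenario")) scenario else
    load_scenario(scenario)
  if (!is.null(seed)) sc$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(sprintf("cannot create directory %s", out_dir),
                 class = "regrowr_io_error")
  }
  run <- run_scenario(sc)
  files <- character(0)
  for (lab in unique(run$cohorts$arm)) {
    co <- dplyr::filter(run$cohorts, .data$arm == lab)
    cohort_path <- file.path(out_dir, paste0(lab, "_cohort.csv"))
    readr::write_csv(
      tibble::tibble(patient = co$patient, B0 = co$B0, outcome = co$outcome,
                     t_R_days = co$t_R),
      cohort_path, progress = FALSE)
    cv <- dplyr::filter(run$curves, .data$arm == lab)
    curve_path <- file.path(out_dir, paste0(lab, "_curve.csv"))
    readr::write_csv(
      tibble::tibble(time_days = cv$time, survival = cv$survival,
                     recurrence_fraction = cv$recurrence),
      curve_path, progress = FALSE)
    files <- c(files, cohort_path, curve_path)
  }
  meta_path <- file.path(out_dir, "metadata.yaml")
  meta <- list(
    scenario = sc$name, seed = sc$seed, n = sc$n, n_reps = sc$n_reps,
    law = sc$model$growth$law, lambda = sc$model$growth$lambda,
    eps_V = sc$model$eps_V, omega_d = sc$model$omega_d,
    viability_term = sc$model$viability_term,
    horizon = sc$horizon, grid_step = sc$grid_step,
    arms = purrr::imap(sc$dists, function(d, i) list(
      label = attr(d, "label") %||% paste0("arm", i),
      convention = d$convention, param1 = d$param1, param2 = d$param2,
      meanlog = d$meanlog, sdlog = d$sdlog))
  )
  yaml::write_yaml(meta, meta_path)
  invisible(c(files, meta_path))
}
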