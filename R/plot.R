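# ggplot2 presentation of curves, bands, sweeps and fits. Time is kept
# in days internally; plots convert to years on the axis.

days_to_years <- function(d) d / 365.25

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_ribbon geom_line
#'   geom_point labs ylim
NULL

#' @export
ggplot2::autoplot

#' Plot an event-free recurrence curve
#'
#' @param object A `recurrence_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recurrence_curve
#' @export
autoplot.recurrence_curve <- function(object, ...) {
  ggplot(object, aes(days_to_years(.data$time), .data$survival)) +
    geom_step(direction = "hv") +
    ylim(0, 1) +
    labs(x = "Time (years)", y = "Event-free fraction",
         title = sprintf("Simulated recurrence curve (n = %d)",
                         attr(object, "n_patients")))
}

#' @export
plot.recurrence_curve <- function(x, ...) print(autoplot(x, ...))

#' Plot a replicate confidence band
#'
#' @param object A `replicate_band` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot replicate_band
#' @export
autoplot.replicate_band <- function(object, ...) {
  ggplot(object, aes(days_to_years(.data$time), .data$mean)) +
    geom_ribbon(aes(ymin = .data$lower95, ymax = .data$upper95),
                alpha = 0.25) +
    geom_line() +
    ylim(0, 1) +
    labs(x = "Time (years)", y = "Event-free fraction",
         title = sprintf("Replicate mean with 95%% band (%d replicates)",
                         attr(object, "n_reps")))
}

#' @export
plot.replicate_band <- function(x, ...) print(autoplot(x, ...))

#' Plot a two-arm comparison
#'
#' @param object An `arm_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot arm_comparison
#' @export
autoplot.arm_comparison <- function(object, ...) {
  ggplot(object$curves,
         aes(days_to_years(.data$time), .data$survival,
             colour = .data$arm)) +
    geom_step(direction = "hv") +
    ylim(0, 1) +
    labs(x = "Time (years)", y = "Event-free fraction", colour = "Arm")
}

#' @export
plot.arm_comparison <- function(x, ...) print(autoplot(x, ...))

#' Plot a parameter sweep
#'
#' @param object A `parameter_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parameter_sweep
#' @export
autoplot.parameter_sweep <- function(object, ...) {
  long <- object |>
    dplyr::mutate(curve = purrr::map(.data$curve, tibble::as_tibble)) |>
    dplyr::select("value", "curve") |>
    tidyr_unnest_curve()
  ggplot(long, aes(days_to_years(.data$time), .data$survival,
                   colour = .data$value, group = .data$value)) +
    geom_step(direction = "hv") +
    ylim(0, 1) +
    labs(x = "Time (years)", y = "Event-free fraction",
         colour = object$param[1])
}

# minimal unnest of the curve list-column (avoids a tidyr dependency for
# one call site)
tidyr_unnest_curve <- function(df) {
  purrr::map2(df$value, df$curve, function(v, cv) {
    dplyr::mutate(cv, value = v, .before = 1)
  }) |> purrr::list_rbind()
}

#' @export
plot.parameter_sweep <- function(x, ...) print(autoplot(x, ...))

#' Plot fitted against observed event-free curves
#'
#' @param object A `regrowth_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regrowth_fit
#' @export
autoplot.regrowth_fit <- function(object, ...) {
  obs <- purrr::imap(object$observed, function(o, i) {
    tibble::tibble(arm = i, time = o$time_days,
                   survival = o$event_free_fraction)
  }) |> purrr::list_rbind()
  ggplot(object$fitted_curves,
         aes(days_to_years(.data$time), .data$survival,
             colour = factor(.data$arm))) +
    geom_line() +
    geom_point(data = obs) +
    ylim(0, 1) +
    labs(x = "Time (years)", y = "Event-free fraction", colour = "Arm")
}

#' @export
plot.regrowth_fit <- function(x, ...) print(autoplot(x, ...))
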