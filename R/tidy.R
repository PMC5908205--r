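# broom-style accessors and ggplot2 graphics for experiment results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an experiment result
#'
#' One row per repeat x trial with latency, guidance and reward flags.
#'
#' @param x a [run_experiment()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.wm_experiment <- function(x, ...) x$trials

#' One-row summary of an experiment result
#'
#' @param x a [run_experiment()] result.
#' @param ... unused.
#' @return a tibble with experiment, group, condition, repeats, seed, mean
#'   latency and the fraction of guided (timed-out) trials.
#' @export
glance.wm_experiment <- function(x, ...) {
  esc <- dplyr::filter(x$trials, .data$platform_present)
  tibble::tibble(
    experiment = x$experiment, group = x$group,
    condition = x$condition %||% NA_character_,
    n_repeats = x$n_repeats, master_seed = x$master_seed,
    mean_latency = mean(esc$latency), frac_guided = mean(esc$guided))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Learning-curve plot of escape latencies
#'
#' Mean escape latency (+/- standard error over repeats) by trial or
#' session.
#'
#' @param x a [run_experiment()] result.
#' @param by `"trial"` or `"session"`.
#' @return a ggplot object.
#' @export
plot_latencies <- function(x, by = c("trial", "session")) {
  by <- match.arg(by)
  lat <- escape_latencies(x, by = if (by == "trial") "trial" else "session")
  key <- if (by == "trial") "trial_global" else "session"
  agg <- dplyr::summarise(
    dplyr::group_by(lat, .data[[key]]),
    mean = mean(.data$latency),
    se = stats::sd(.data$latency) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data[[key]], y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = by, y = "escape latency (timesteps)",
                  title = paste("Experiment", x$experiment, "-", x$group)) +
    ggplot2::theme_minimal()
}

#' Strategy selection-rate plot
#'
#' Mean selection rate of each strategy across sessions.
#'
#' @param x a [run_experiment()] result.
#' @return a ggplot object.
#' @export
plot_selection_rates <- function(x) {
  sel <- selection_rates(x, by = "session")
  agg <- dplyr::summarise(
    dplyr::group_by(sel, .data$session, .data$module),
    rate = mean(.data$rate, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$session, y = .data$rate,
                                    colour = .data$module)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "session", y = "selection rate", colour = "strategy") +
    ggplot2::theme_minimal()
}

#' Trajectory plot of a recorded trial
#'
#' @param x a [run_experiment()] result with recorded steps.
#' @param rep repeat index.
#' @param trial_global global trial index (must have been recorded).
#' @return a ggplot object (arena wall, trajectory coloured by the selected
#'   strategy, platform position).
#' @export
plot_trajectory <- function(x, rep, trial_global) {
  st <- x$steps[x$steps$rep == rep & x$steps$trial_global == trial_global, ]
  if (nrow(st) == 0) stop("no recorded steps for this repeat/trial")
  tr <- x$trials[x$trials$rep == rep & x$trials$trial_global == trial_global, ]
  th <- seq(0, 2 * pi, length.out = 181)
  wall <- data.frame(x = x$params$arena_radius * cos(th),
                     y = x$params$arena_radius * sin(th))
  p <- ggplot2::ggplot(st, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = wall, colour = "grey40") +
    ggplot2::geom_path(ggplot2::aes(colour = .data$module)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "strategy") + ggplot2::theme_minimal()
  if (tr$platform_present) {
    p <- p + ggplot2::annotate("point", x = tr$platform_x, y = tr$platform_y,
                               shape = 21, size = 4, stroke = 1.2)
  }
  p
}

#' @export
autoplot.wm_experiment <- function(object, ...) plot_latencies(object, ...)
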