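#' Tidy methods for swarmreg result objects
#'
#' `tidy()` returns the per-iteration or per-run table of a result as a
#' tibble; `glance()` returns a one-row summary; `autoplot()` draws the
#' standard diagnostic plot (convergence trace, per-run error distribution,
#' or sweep curve).
#'
#' @param x A `swarm_fit`, `benchmark_result` or `registration_result`.
#' @param ... Unused, for generic consistency.
#' @return A tibble (`tidy`, `glance`) or a ggplot object (`autoplot`).
#' @name swarmreg-tidiers
NULL

#' @rdname swarmreg-tidiers
#' @export
tidy.swarm_fit <- function(x, ...) {
  x$trace
}

#' @rdname swarmreg-tidiers
#' @export
glance.swarm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_particles = x$control$n_particles,
    n_subpopulations = x$control$n_subpopulations,
    iterations = x$control$iterations,
    seed = x$control$seed,
    best_score = x$best_score
  )
}

#' @rdname swarmreg-tidiers
#' @export
autoplot.swarm_fit <- function(x, ...) {
  ggplot2::ggplot(x$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Best objective value",
                  title = paste("Convergence trace,", toupper(x$method))) +
    ggplot2::theme_minimal()
}

#' @rdname swarmreg-tidiers
#' @export
tidy.benchmark_result <- function(x, ...) {
  x$runs
}

#' @rdname swarmreg-tidiers
#' @export
glance.benchmark_result <- function(x, ...) {
  tibble::tibble(
    function_name = x$function_name,
    method = x$method,
    n_runs = x$n_runs,
    n_particles = x$control$n_particles,
    n_subpopulations = if (x$method == "pso") 1L else x$control$n_subpopulations,
    iterations = x$control$iterations,
    mean_relative_error_percent = x$mean_relative_error_percent
  )
}

#' @rdname swarmreg-tidiers
#' @export
autoplot.benchmark_result <- function(x, ...) {
  ggplot2::ggplot(x$runs,
                  ggplot2::aes(x = .data$relative_error_percent)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = x$mean_relative_error_percent,
                        linetype = "dashed") +
    ggplot2::labs(x = "Relative error (%)", y = "Runs",
                  title = paste0(x$function_name, ", ", toupper(x$method),
                                 ": per-run recovery error")) +
    ggplot2::theme_minimal()
}

#' @rdname swarmreg-tidiers
#' @export
tidy.registration_result <- function(x, ...) {
  x$trace
}

#' @rdname swarmreg-tidiers
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    bins = x$bins,
    best_mi = x$best_mi,
    tx = x$best_transform$translation[1],
    ty = x$best_transform$translation[2],
    tz = x$best_transform$translation[3],
    rx = x$best_transform$angles[1],
    ry = x$best_transform$angles[2],
    rz = x$best_transform$angles[3],
    diff_translation = x$diff_translation,
    diff_rotation = x$diff_rotation
  )
}

#' @rdname swarmreg-tidiers
#' @export
autoplot.registration_result <- function(x, ...) {
  ggplot2::ggplot(x$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_mi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Best mutual information (bits)",
                  title = "Registration convergence") +
    ggplot2::theme_minimal()
}

#' Plot a subpopulation sweep
#'
#' Line plot of mean recovery error against the number of subpopulations, on
#' a log2 x-axis.
#'
#' @param sweep A tibble from [subpopulation_sweep()].
#' @return A ggplot object.
#' @export
plot_subpopulation_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$n_subpopulations,
                               y = .data$mean_relative_error_percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "Subpopulations (N)", y = "Mean relative error (%)",
                  title = "Accuracy vs. number of subpopulations") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
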