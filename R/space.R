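#' Define a bounded search space
#'
#' A search space is a box `[lower, upper]` in `d` dimensions plus the
#' optimization sense. Optimizers in this package work internally as
#' maximizers; minimization problems are handled by negating the objective at
#' this boundary, so user-facing scores are always on the objective's own
#' scale.
#'
#' @param lower,upper Numeric vectors of per-dimension bounds. Scalars are
#'   recycled to the length of the other argument. `lower[i] < upper[i]` must
#'   hold for every dimension.
#' @param sense `"minimize"` or `"maximize"`.
#'
#' @return An object of class `search_space` with fields `lower`, `upper`,
#'   `dimension` and `sense`.
#' @examples
#' search_space(rep(-5.12, 3), rep(5.11, 3))
#' @export
search_space <- function(lower, upper, sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  if (length(lower) == 1L && length(upper) > 1L) lower <- rep(lower, length(upper))
  if (length(upper) == 1L && length(lower) > 1L) upper <- rep(upper, length(lower))
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length.", call. = FALSE)
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("Bounds must be finite.", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("Every lower bound must be strictly below its upper bound.", call. = FALSE)
  }
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         dimension = length(lower), sense = sense),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> ", x$dimension, "-d, sense = ", x$sense, "\n", sep = "")
  cat("  lower:", format(x$lower, trim = TRUE), "\n")
  cat("  upper:", format(x$upper, trim = TRUE), "\n")
  invisible(x)
}

#' Control parameters for the swarm optimizers
#'
#' Collects the tunable parameters of [pso_optimize()] and [hpso_optimize()].
#' Defaults follow the published protocol: acceleration constants
#' `c1 = c2 = 2`, inertia weight decreasing linearly from `w_max = 0.98` to
#' `w_min = 0.4` over the run, 56 particles in 4 subpopulations for 100
#' iterations.
#'
#' @param n_particles Total number of particles (partitioned as evenly as
#'   possible across subpopulations; sizes differ by at most one and every
#'   subpopulation must keep at least 2 members).
#' @param n_subpopulations Number of subpopulations (islands). `1` reduces the
#'   hybrid optimizer to plain PSO.
#' @param iterations Number of generations `T`.
#' @param c1,c2 Acceleration constants for the personal-best and group-best
#'   pulls.
#' @param w_min,w_max Inertia-weight bounds; the weight starts at `w_max` and
#'   decreases by `(w_min - w_max) / iterations` each generation, clamped to
#'   `[w_min, w_max]`.
#' @param v_max_fraction Velocity clamp, as a fraction of the per-dimension
#'   search range.
#' @param seed Integer seed; all randomness in a run flows from it.
#' @param crossover Logical; apply the arithmetic-crossover / worst-replacement
#'   step between the two best subpopulation leaders once per generation
#'   (ignored, with a silent skip, when fewer than 2 subpopulations exist).
#' @param rand_per_dimension Logical; if `FALSE` (default) the two `rand`
#'   factors of the velocity update are scalar per particle per generation,
#'   matching the scalar notation of the update rule. If `TRUE`, fresh draws
#'   are made per dimension.
#' @param boundary How to treat the velocity of a particle whose position
#'   was clamped to the search box: `"clamp"` (default) leaves it unchanged;
#'   `"reflect"` negates the offending components so bounds do not become
#'   absorbing. [register_volumes()] defaults to `"reflect"`.
#'
#' @return A list of class `swarm_control`.
#' @examples
#' swarm_control(n_particles = 56, n_subpopulations = 4, iterations = 100)
#' @export
swarm_control <- function(n_particles = 56L, n_subpopulations = 4L,
                          iterations = 100L, c1 = 2, c2 = 2,
                          w_min = 0.4, w_max = 0.98, v_max_fraction = 0.5,
                          seed = 1L, crossover = TRUE,
                          rand_per_dimension = FALSE,
                          boundary = c("clamp", "reflect")) {
  boundary <- match.arg(boundary)
  n_particles <- as.integer(n_particles)
  n_subpopulations <- as.integer(n_subpopulations)
  iterations <- as.integer(iterations)
  if (n_particles < 2L) stop("Need at least 2 particles.", call. = FALSE)
  if (n_subpopulations < 1L) stop("Need at least 1 subpopulation.", call. = FALSE)
  if (iterations < 1L) stop("Need at least 1 iteration.", call. = FALSE)
  if (!(w_min > 0 && w_min <= w_max)) {
    stop("Inertia bounds must satisfy 0 < w_min <= w_max.", call. = FALSE)
  }
  if (v_max_fraction <= 0) stop("`v_max_fraction` must be positive.", call. = FALSE)
  sizes <- subpopulation_sizes(n_particles, n_subpopulations)
  if (min(sizes) < 2L) {
    stop("Every subpopulation needs at least 2 members; ", n_particles,
         " particles cannot fill ", n_subpopulations, " subpopulations.",
         call. = FALSE)
  }
  structure(
    list(n_particles = n_particles, n_subpopulations = n_subpopulations,
         iterations = iterations, c1 = c1, c2 = c2,
         w_min = w_min, w_max = w_max, v_max_fraction = v_max_fraction,
         seed = as.integer(seed), crossover = isTRUE(crossover),
         rand_per_dimension = isTRUE(rand_per_dimension),
         boundary = boundary),
    class = "swarm_control"
  )
}

# Even partition: sizes differ by at most 1.
subpopulation_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  as.integer(base + (seq_len(k) <= extra))
}
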