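#' @title Swarm state and the particle update machinery
#' @description Internal-but-exported building blocks of the optimizers:
#'   initialization, the per-subpopulation particle update, the inertia
#'   schedule, and the crossover step. [pso_optimize()] and [hpso_optimize()]
#'   drive these; they are exported so each rule can be exercised directly.
#' @name swarm-state
NULL

# Evaluate the objective at a matrix of positions (rows = particles), in the
# *internal* maximize sense. A vectorized objective (attribute
# "vectorized" == TRUE) is called once on the matrix; otherwise row-wise.
eval_objective <- function(objective, pos, sign) {
  vals <- if (isTRUE(attr(objective, "vectorized"))) {
    as.numeric(objective(pos))
  } else {
    vapply(seq_len(nrow(pos)), function(i) as.numeric(objective(pos[i, ])), 0)
  }
  if (length(vals) != nrow(pos)) {
    stop("Objective returned ", length(vals), " values for ", nrow(pos),
         " positions; it must map one position to one finite number.",
         call. = FALSE)
  }
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    stop("Objective returned a non-finite value at position (",
         paste(signif(pos[bad[1L], ], 6), collapse = ", "), ").",
         call. = FALSE)
  }
  sign * vals
}

objective_sign <- function(space) if (space$sense == "maximize") 1 else -1

#' Initialize a swarm
#'
#' Seeds the RNG from `control$seed`, draws positions uniformly within the
#' bounds and velocities uniformly in `[-v_max, +v_max]` per dimension
#' (`v_max = v_max_fraction * (upper - lower)`), evaluates every particle
#' once, and sets all personal, subpopulation and global bests from that first
#' evaluation. The inertia weight starts at `w_max`.
#'
#' @param space A [search_space()].
#' @param control A [swarm_control()].
#' @param objective Function mapping an in-bounds numeric vector to a finite
#'   scalar. May carry attribute `vectorized = TRUE`, in which case it is
#'   called with a matrix (rows = positions) and must return one value per row.
#'
#' @return A `swarm_state` list: position/velocity matrices, personal bests,
#'   subpopulation assignment and bests, global best, inertia weight and
#'   iteration counter. Scores are stored internally in maximize sense; use
#'   the `sign` field to map back.
#' @export
initialize_swarm <- function(space, control, objective) {
  stopifnot(inherits(space, "search_space"), inherits(control, "swarm_control"))
  set.seed(control$seed)
  n <- control$n_particles
  d <- space$dimension
  k <- control$n_subpopulations
  sizes <- subpopulation_sizes(n, k)
  if (min(sizes) < 2L) {
    stop("Every subpopulation needs at least 2 members.", call. = FALSE)
  }
  rng <- space$upper - space$lower
  v_max <- control$v_max_fraction * rng

  pos <- matrix(runif(n * d), n, d)
  pos <- sweep(sweep(pos, 2, rng, "*"), 2, space$lower, "+")
  vel <- matrix(runif(n * d, -1, 1), n, d)
  vel <- sweep(vel, 2, v_max, "*")

  sgn <- objective_sign(space)
  scores <- eval_objective(objective, pos, sgn)

  sub_id <- rep.int(seq_len(k), times = sizes)
  sub_best_score <- rep(-Inf, k)
  sub_best_position <- matrix(NA_real_, k, d)
  sub_best_member <- integer(k)
  for (kk in seq_len(k)) {
    idx <- which(sub_id == kk)
    j <- idx[which.max(scores[idx])]
    sub_best_score[kk] <- scores[j]
    sub_best_position[kk, ] <- pos[j, ]
    sub_best_member[kk] <- j
  }
  g <- which.max(sub_best_score)

  structure(
    list(position = pos, velocity = vel,
         pbest_position = pos, pbest_score = scores,
         sub_id = sub_id, n_subpopulations = k,
         sub_best_position = sub_best_position,
         sub_best_score = sub_best_score,
         sub_best_member = sub_best_member,
         gbest_position = sub_best_position[g, ],
         gbest_score = sub_best_score[g],
         inertia = control$w_max, iteration = 0L,
         sign = sgn, v_max = v_max),
    class = "swarm_state"
  )
}

# Velocity/position update for one particle block; pure arithmetic so it can
# be checked against a hand calculation with stubbed rand values.
velocity_update <- function(pos, vel, pbest, attractor, w, c1, c2, r1, r2) {
  vel_new <- w * vel + c1 * r1 * (pbest - pos) + c2 * r2 * (attractor - pos)
  list(velocity = vel_new, position = pos + vel_new)
}

clamp_rows <- function(m, lower, upper) {
  clamp_matrix(m, rep(lower, length.out = ncol(m)),
               rep(upper, length.out = ncol(m)))
}

#' One particle-swarm update of a subpopulation
#'
#' Applies the inertia-weighted velocity update to every member of
#' subpopulation `k`: each particle is pulled toward its personal best and
#' toward the subpopulation's own best (the group attractor — the global best
#' across subpopulations is only a promotion target, so that islands stay
#' diverse). Velocities are clamped componentwise to `±v_max`, positions to
#' the bounds; personal and subpopulation bests are refreshed, and the global
#' best is promoted when the subpopulation best improves on it.
#'
#' @param state A `swarm_state` from [initialize_swarm()].
#' @param k Subpopulation index.
#' @inheritParams initialize_swarm
#'
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(state, k, objective, space, control) {
  idx <- which(state$sub_id == k)
  m <- length(idx)
  d <- space$dimension
  if (control$rand_per_dimension) {
    r1 <- matrix(runif(m * d), m, d)
    r2 <- matrix(runif(m * d), m, d)
  } else {
    r1 <- runif(m)
    r2 <- runif(m)
  }
  attractor <- matrix(state$sub_best_position[k, ], m, d, byrow = TRUE)
  upd <- velocity_update(state$position[idx, , drop = FALSE],
                         state$velocity[idx, , drop = FALSE],
                         state$pbest_position[idx, , drop = FALSE],
                         attractor, state$inertia, control$c1, control$c2,
                         r1, r2)
  vel <- clamp_rows(upd$velocity, -state$v_max, state$v_max)
  raw <- state$position[idx, , drop = FALSE] + vel
  pos <- clamp_rows(raw, space$lower, space$upper)
  if (identical(control$boundary, "reflect")) {
    # reflect velocity components that drove a particle into a wall, so
    # bounds do not become absorbing: a pinned particle with unchanged
    # outward velocity would otherwise stay glued to the boundary
    hit <- raw != pos
    vel[hit] <- -vel[hit]
  }
  scores <- eval_objective(objective, pos, state$sign)

  state$velocity[idx, ] <- vel
  state$position[idx, ] <- pos
  better <- scores > state$pbest_score[idx]
  if (any(better)) {
    rows <- idx[better]
    state$pbest_position[rows, ] <- pos[better, , drop = FALSE]
    state$pbest_score[rows] <- scores[better]
    b <- which.max(state$pbest_score[idx])
    if (state$pbest_score[idx][b] > state$sub_best_score[k]) {
      state$sub_best_score[k] <- state$pbest_score[idx][b]
      state$sub_best_position[k, ] <- state$pbest_position[idx[b], ]
      state$sub_best_member[k] <- idx[b]
    }
  }
  if (state$sub_best_score[k] > state$gbest_score) {
    state$gbest_score <- state$sub_best_score[k]
    state$gbest_position <- state$sub_best_position[k, ]
  }
  state
}

#' Advance the inertia weight one generation
#'
#' The weight follows a linear schedule `w <- w + (w_min - w_max) / T`,
#' clamped to `[w_min, w_max]`: it starts at `w_max` and reaches `w_min`
#' exactly after `T` generations.
#'
#' @inheritParams pso_step
#' @return The state with the updated weight.
#' @export
update_inertia <- function(state, control) {
  dw <- (control$w_min - control$w_max) / control$iterations
  state$inertia <- min(max(state$inertia + dw, control$w_min), control$w_max)
  state
}

#' Arithmetic crossover of two parent vectors
#'
#' Offspring are the pair of complementary convex combinations
#' `r * x_i + (1 - r) * x_j` and `r * x_j + (1 - r) * x_i` with one shared
#' uniform draw `r`, so each offspring coordinate lies within the
#' componentwise interval spanned by the parents.
#'
#' @param parent_i,parent_j Numeric vectors of equal length.
#' @param r Mixing weight in `[0, 1]`; a fresh uniform draw by default.
#' @return A list with elements `offspring_i` and `offspring_j`.
#' @examples
#' arithmetic_crossover(c(0, 0), c(2, 4), r = 0.25)
#' @export
arithmetic_crossover <- function(parent_i, parent_j, r = runif(1)) {
  if (length(parent_i) != length(parent_j)) {
    stop("Parents must have the same dimension.", call. = FALSE)
  }
  list(offspring_i = r * parent_i + (1 - r) * parent_j,
       offspring_j = r * parent_j + (1 - r) * parent_i)
}

#' Recombine two parent velocities
#'
#' Both offspring velocities point along the parents' summed direction
#' `V = (v_i + v_j) / ||v_i + v_j||`, each keeping its own parent's speed:
#' `v_i' = ||v_i|| V`, `v_j' = ||v_j|| V`. When the parents cancel exactly
#' (`||v_i + v_j|| = 0`) no common direction exists and the parent velocities
#' are returned unchanged.
#'
#' @param v_i,v_j Numeric velocity vectors of equal length.
#' @return A list with elements `v_i` and `v_j`.
#' @examples
#' recombine_velocities(c(3, 0), c(0, 4))
#' @export
recombine_velocities <- function(v_i, v_j) {
  if (length(v_i) != length(v_j)) {
    stop("Velocities must have the same dimension.", call. = FALSE)
  }
  s <- v_i + v_j
  ns <- sqrt(sum(s^2))
  if (ns == 0) {
    return(list(v_i = v_i, v_j = v_j))
  }
  V <- s / ns
  list(v_i = sqrt(sum(v_i^2)) * V, v_j = sqrt(sum(v_j^2)) * V)
}

#' Crossover step between the two best subpopulations
#'
#' Subpopulation bests are sorted; the leaders of the top two subpopulations
#' serve as parents. Their positions are mixed by [arithmetic_crossover()]
#' (one shared `r` per event) and the velocities of the particles holding
#' those bests by [recombine_velocities()]. Each offspring then replaces the
#' worst member (lowest personal-best score, ties broken by lowest index) of
#' its parent's subpopulation, and that member's personal best is reset to
#' the offspring's own evaluation. With fewer than two subpopulations the
#' step is silently skipped.
#'
#' @inheritParams initialize_swarm
#' @param state A `swarm_state`.
#' @return The updated `swarm_state`.
#' @export
crossover_step <- function(state, objective, space, control) {
  if (state$n_subpopulations < 2L) {
    return(state)
  }
  ord <- order(state$sub_best_score, decreasing = TRUE)
  ki <- ord[1L]
  kj <- ord[2L]
  off <- arithmetic_crossover(state$sub_best_position[ki, ],
                              state$sub_best_position[kj, ])
  voff <- recombine_velocities(state$velocity[state$sub_best_member[ki], ],
                               state$velocity[state$sub_best_member[kj], ])
  pos <- clamp_rows(rbind(off$offspring_i, off$offspring_j),
                    space$lower, space$upper)
  vel <- clamp_rows(rbind(voff$v_i, voff$v_j), -state$v_max, state$v_max)
  scores <- eval_objective(objective, pos, state$sign)

  for (s in 1:2) {
    kk <- c(ki, kj)[s]
    idx <- which(state$sub_id == kk)
    worst <- idx[which.min(state$pbest_score[idx])]
    state$position[worst, ] <- pos[s, ]
    state$velocity[worst, ] <- vel[s, ]
    state$pbest_position[worst, ] <- pos[s, ]
    state$pbest_score[worst] <- scores[s]
    if (scores[s] > state$sub_best_score[kk]) {
      state$sub_best_score[kk] <- scores[s]
      state$sub_best_position[kk, ] <- pos[s, ]
      state$sub_best_member[kk] <- worst
    }
    if (state$sub_best_score[kk] > state$gbest_score) {
      state$gbest_score <- state$sub_best_score[kk]
      state$gbest_position <- state$sub_best_position[kk, ]
    }
  }
  state
}

swarm_engine <- function(objective, space, control, crossover) {
  state <- initialize_swarm(space, control, objective)
  t_total <- control$iterations
  trace_iter <- integer(t_total + 1L)
  trace_w <- numeric(t_total + 1L)
  trace_best <- numeric(t_total + 1L)
  trace_iter[1L] <- 0L
  trace_w[1L] <- state$inertia
  trace_best[1L] <- state$sign * state$gbest_score
  for (t in seq_len(t_total)) {
    for (k in seq_len(control$n_subpopulations)) {
      state <- pso_step(state, k, objective, space, control)
    }
    if (crossover) {
      state <- crossover_step(state, objective, space, control)
    }
    state <- update_inertia(state, control)
    state$iteration <- t
    trace_iter[t + 1L] <- t
    trace_w[t + 1L] <- state$inertia
    trace_best[t + 1L] <- state$sign * state$gbest_score
  }
  structure(
    list(best_position = as.numeric(state$gbest_position),
         best_score = state$sign * state$gbest_score,
         trace = tibble::tibble(iteration = trace_iter, inertia = trace_w,
                                best_score = trace_best),
         space = space, control = control,
         method = if (crossover && control$n_subpopulations > 1L) "hpso" else "pso",
         final_state = state),
    class = "swarm_fit"
  )
}

#' Hybrid particle swarm optimization
#'
#' Runs the hybrid optimizer: the swarm is partitioned into subpopulations,
#' each updated by the inertia-weighted particle swarm rule with its own best
#' as the group attractor; subpopulation bests that improve on the global
#' best are promoted; once per generation the two best subpopulation leaders
#' are crossed over (arithmetic position crossover, speed-preserving velocity
#' recombination) and the offspring replace the worst members of their
#' subpopulations.
#'
#' @inheritParams initialize_swarm
#' @return A `swarm_fit` object with `best_position`, `best_score` (in the
#'   space's own sense), a per-generation `trace` tibble
#'   (`iteration`, `inertia`, `best_score`), and the configuration. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' sp <- search_space(rep(-5.12, 3), rep(5.11, 3))
#' fit <- hpso_optimize(function(x) sum(x^2), sp,
#'                      swarm_control(iterations = 50, seed = 7))
#' fit$best_score
#' @export
hpso_optimize <- function(objective, space, control = swarm_control()) {
  swarm_engine(objective, space, control,
               crossover = control$crossover && control$n_subpopulations > 1L)
}

#' Plain particle swarm optimization
#'
#' The classic single-population optimizer: identical to [hpso_optimize()]
#' with one subpopulation and no crossover, so the whole swarm shares one
#' group attractor.
#'
#' @inheritParams initialize_swarm
#' @return A `swarm_fit`; see [hpso_optimize()].
#' @export
pso_optimize <- function(objective, space, control = swarm_control()) {
  control$n_subpopulations <- 1L
  control$crossover <- FALSE
  swarm_engine(objective, space, control, crossover = FALSE)
}

#' @export
print.swarm_fit <- function(x, ...) {
  cat("<swarm_fit> method =", x$method,
      "| particles =", x$control$n_particles,
      "| subpopulations =", x$control$n_subpopulations,
      "| iterations =", x$control$iterations, "\n")
  cat("  best score:", format(x$best_score), "\n")
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "), "\n")
  invisible(x)
}
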