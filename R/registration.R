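#' Default parameter bounds for rigid registration
#'
#' The search box over the six rigid parameters: translations within plus or
#' minus half the fixed image's field of view (mm) on each axis, in-plane
#' rotation (about z) within plus or minus 180 degrees, out-of-plane
#' rotations (about x and y) within plus or minus 30 degrees.
#'
#' @param fixed The fixed [volume3d()].
#' @return A data frame with columns `parameter`, `lower`, `upper` and rows
#'   `tx`, `ty`, `tz`, `rx`, `ry`, `rz`.
#' @export
default_parameter_bounds <- function(fixed) {
  stopifnot(inherits(fixed, "volume3d"))
  half_fov <- dim(fixed$data) * fixed$spacing / 2
  data.frame(
    parameter = c("tx", "ty", "tz", "rx", "ry", "rz"),
    lower = c(-half_fov, -30, -30, -180),
    upper = c(half_fov, 30, 30, 180)
  )
}

check_bounds_frame <- function(bounds) {
  need <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (is.matrix(bounds)) {
    bounds <- data.frame(parameter = rownames(bounds),
                         lower = bounds[, 1], upper = bounds[, 2])
  }
  if (!all(need %in% bounds$parameter)) {
    stop("Bounds must cover parameters ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  bounds <- bounds[match(need, bounds$parameter), ]
  if (any(bounds$lower >= bounds$upper)) {
    stop("Every lower bound must be below its upper bound.", call. = FALSE)
  }
  bounds
}

#' Mutual information between a fixed volume and a transformed moving volume
#'
#' The registration objective at a single transform: the moving volume is
#' backward-warped onto the fixed grid through `transform`, voxels mapped
#' outside the moving field of view are excluded by the validity mask, and
#' the plug-in mutual information of the remaining intensity pairs is
#' computed with bin edges pinned to the two volumes' global intensity
#' ranges (so values are comparable across candidate transforms).
#'
#' @param fixed,moving [volume3d()] objects.
#' @param transform A [rigid_transform()].
#' @param bins Histogram bins per image.
#' @param range_fixed,range_moving Length-2 intensity ranges fixing the bin
#'   edges; default to each volume's full observed range.
#' @return Mutual information in bits; `0` when no voxel overlaps.
#' @export
registration_mi <- function(fixed, moving, transform, bins = 64L,
                            range_fixed = range(fixed$data),
                            range_moving = range(moving$data)) {
  warped <- resample(moving, transform, fixed, fill = 0)
  if (!any(warped$mask)) {
    return(0)
  }
  h <- joint_histogram(fixed$data, warped$data, bins = bins,
                       mask = warped$mask,
                       range_a = range_fixed, range_b = range_moving)
  mutual_information(h)
}

#' Register a moving volume to a fixed volume
#'
#' Estimates the six rigid parameters (three translations in mm, three Euler
#' angles in degrees, rotation about the fixed volume's center) that
#' maximize the mutual information between the fixed image and the
#' backward-warped moving image, using the hybrid particle swarm optimizer
#' (or plain PSO). Internally the six heterogeneous parameters are
#' normalized to `[0, 1]` so a single velocity clamp governs them all.
#'
#' @param fixed,moving [volume3d()] objects.
#' @param bounds Search box as produced by [default_parameter_bounds()] (the
#'   default), or any data frame/matrix with the same parameters.
#' @param bins Joint-histogram bins per image.
#' @param control A [swarm_control()]; the registration default keeps the
#'   published protocol (56 particles, 4 subpopulations, 100 iterations) but
#'   draws the velocity-update `rand` factors per dimension — with six
#'   heterogeneous parameters, scalar draws move each particle only along
#'   the line toward its attractors and refine the rotations poorly.
#' @param method `"hpso"` (default) or `"pso"`.
#' @param truth Optional ground-truth [rigid_transform()]; when supplied the
#'   result carries `diff_translation` and `diff_rotation` (see
#'   [parameter_diff()]).
#' @return A `registration_result`: `best_transform`, `best_mi` (bits),
#'   per-generation `trace` tibble (`iteration`, `inertia`, `best_mi`), the
#'   resolved `bounds`, `bins`, `method`, `control`, and the diff columns
#'   when `truth` is given. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' spec <- phantom_spec(size = c(32, 32, 8), noise_sd = 0)
#' pair <- make_multimodal_pair(spec, rigid_transform(translation = c(6, 3, 0)))
#' fit <- register_volumes(pair$fixed, pair$moving,
#'                         control = swarm_control(n_particles = 24,
#'                                                 iterations = 30, seed = 2),
#'                         truth = pair$truth)
#' fit$diff_translation
#' }
#' @export
register_volumes <- function(fixed, moving, bounds = default_parameter_bounds(fixed),
                             bins = 64L,
                             control = swarm_control(rand_per_dimension = TRUE,
                                                     boundary = "reflect"),
                             method = c("hpso", "pso"), truth = NULL) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"))
  method <- match.arg(method)
  bounds <- check_bounds_frame(bounds)
  lower <- bounds$lower
  upper <- bounds$upper
  width <- upper - lower
  center <- volume_center(fixed)
  range_fixed <- range(fixed$data)
  range_moving <- range(moving$data)

  # Precompute everything reusable across the thousands of MI evaluations;
  # the per-candidate work (map, sample, bin, entropies) runs in one
  # compiled pass over the fixed grid.
  ia_all <- bin_index(as.numeric(fixed$data), range_fixed, bins)
  mdim <- dim(moving$data)
  mdat <- as.numeric(moving$data)
  fdim <- dim(fixed$data)
  mwidth <- range_moving[2] - range_moving[1]

  mi_of_params <- function(theta) {
    R <- rotation_matrix(theta[4], theta[5], theta[6])
    offset <- as.numeric(center + theta[1:3] - R %*% center)
    mi_rigid_kernel(mdat, mdim, moving$origin, moving$spacing,
                    fdim, fixed$origin, fixed$spacing, ia_all,
                    R, offset, bins, range_moving[1], mwidth)$mi
  }

  objective <- function(u) mi_of_params(lower + u * width)
  space <- search_space(rep(0, 6), rep(1, 6), sense = "maximize")
  fit <- if (method == "hpso") {
    hpso_optimize(objective, space, control)
  } else {
    pso_optimize(objective, space, control)
  }
  if (fit$best_score <= 0) {
    stop("No candidate transform produced overlapping voxels; ",
         "widen the parameter bounds.", call. = FALSE)
  }
  theta <- lower + fit$best_position * width
  best_transform <- rigid_transform(angles = theta[4:6],
                                    translation = theta[1:3],
                                    center = center)
  trace <- fit$trace
  names(trace)[names(trace) == "best_score"] <- "best_mi"
  out <- list(best_transform = best_transform, best_mi = fit$best_score,
              trace = trace, bounds = bounds, bins = bins, method = method,
              control = control, truth = truth,
              diff_translation = NA_real_, diff_rotation = NA_real_)
  class(out) <- "registration_result"
  if (!is.null(truth)) {
    d <- evaluate_against_truth(out, truth)
    out$diff_translation <- d$diff_translation
    out$diff_rotation <- d$diff_rotation
  }
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> method =", toupper(x$method),
      "| bins =", x$bins, "\n")
  cat("  best MI:", format(x$best_mi, digits = 5), "bits\n")
  cat("  translation (mm):",
      paste(signif(x$best_transform$translation, 5), collapse = ", "), "\n")
  cat("  rotation (deg):  ",
      paste(signif(x$best_transform$angles, 5), collapse = ", "), "\n")
  if (!is.na(x$diff_translation)) {
    cat("  diff vs truth: translation", signif(x$diff_translation, 4),
        "| rotation", signif(x$diff_rotation, 4), "\n")
  }
  invisible(x)
}

#' Per-block parameter recovery error ("diff")
#'
#' The scalar error reported per parameter block (translation triple or
#' rotation triple) when ground truth is known: the Euclidean norm of the
#' 3-vector error divided by 3,
#' `diff = ||estimate - truth||_2 / 3`.
#'
#' @param estimate,truth Length-3 numeric vectors (one parameter block).
#' @return Non-negative scalar in the block's own units (mm or degrees).
#' @examples
#' parameter_diff(c(20.04, 11.16, 1.75), c(20, 10, 2))  # 0.40
#' @export
parameter_diff <- function(estimate, truth) {
  if (length(estimate) != 3L || length(truth) != 3L) {
    stop("`estimate` and `truth` must each have length 3.", call. = FALSE)
  }
  sqrt(sum((estimate - truth)^2)) / 3
}

#' Evaluate a recovered transform against ground truth
#'
#' Applies [parameter_diff()] separately to the translation triple (mm) and
#' the rotation-angle triple (degrees). Angles are compared as-is, without
#' modular wrapping.
#'
#' @param x A `registration_result` or a [rigid_transform()].
#' @param truth The ground-truth [rigid_transform()].
#' @return A one-row tibble with `diff_translation` and `diff_rotation`.
#' @examples
#' evaluate_against_truth(rigid_transform(c(-0.25, -0.48, 117.57)),
#'                        rigid_transform(c(0, 0, 120)))
#' @export
evaluate_against_truth <- function(x, truth) {
  est <- if (inherits(x, "registration_result")) x$best_transform else x
  stopifnot(inherits(est, "rigid_transform3d"),
            inherits(truth, "rigid_transform3d"))
  tibble::tibble(
    diff_translation = parameter_diff(est$translation, truth$translation),
    diff_rotation = parameter_diff(est$angles, truth$angles)
  )
}
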