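#' Euler rotation matrix for a rigid 3D transform
#'
#' Builds the 3x3 rotation matrix from three Euler angles (degrees) about the
#' x, y and z axes. The composition is the transpose of
#' `Rx(alpha) %*% Ry(beta) %*% Rz(gamma)`, written out:
#' row 1 `(cb*cg, ca*sg + sa*sb*cg, sa*sg - ca*sb*cg)`,
#' row 2 `(-cb*sg, ca*cg - sa*sb*sg, sa*cg + ca*sb*sg)`,
#' row 3 `(sb, -sa*cb, ca*cb)`.
#' The result is orthonormal with determinant +1 for any angle triple.
#'
#' @param alpha,beta,gamma Rotation angles in degrees about x, y, z.
#' @return A 3x3 rotation matrix.
#' @examples
#' rotation_matrix(0, 0, 90)
#' @export
rotation_matrix <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180
  b <- beta * pi / 180
  g <- gamma * pi / 180
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(
    cb * cg,  ca * sg + sa * sb * cg,  sa * sg - ca * sb * cg,
    -cb * sg, ca * cg - sa * sb * sg,  sa * cg + ca * sb * sg,
    sb,       -sa * cb,                ca * cb
  ), nrow = 3, byrow = TRUE)
}

#' Rigid 3D transform (6 degrees of freedom)
#'
#' A rotation about a fixed world-space center followed by a translation:
#' `T(p) = R (p - center) + center + t`. Angles are in degrees at every
#' interface (converted to radians only inside [rotation_matrix()]);
#' translations and the center are in world millimetres.
#'
#' @param angles Length-3 numeric: rotations about x, y, z in degrees.
#' @param translation Length-3 numeric translation in mm.
#' @param center Length-3 world point the rotation pivots about (commonly the
#'   volume center; see [volume_center()]).
#' @return An object of class `rigid_transform3d`.
#' @examples
#' tr <- rigid_transform(angles = c(0, 0, 120), translation = c(20, 10, 2))
#' apply_transform(tr, c(1, 2, 3))
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3, length(translation) == 3, length(center) == 3)
  if (!all(is.finite(c(angles, translation, center)))) {
    stop("Transform parameters must be finite.", call. = FALSE)
  }
  structure(
    list(angles = as.numeric(angles), translation = as.numeric(translation),
         center = as.numeric(center)),
    class = "rigid_transform3d"
  )
}

#' @export
print.rigid_transform3d <- function(x, ...) {
  cat("<rigid_transform3d>\n")
  cat("  angles (deg):   ", paste(signif(x$angles, 6), collapse = ", "), "\n")
  cat("  translation (mm):", paste(signif(x$translation, 6), collapse = ", "), "\n")
  cat("  center (mm):    ", paste(signif(x$center, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a rigid transform to world points
#'
#' @param transform A [rigid_transform()].
#' @param points A length-3 vector or an `n x 3` matrix (or data frame) of
#'   world coordinates in mm.
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform3d"))
  single <- is.null(dim(points))
  p <- if (single) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  if (ncol(p) != 3) stop("Points must have 3 coordinates.", call. = FALSE)
  R <- rotation_matrix(transform$angles[1], transform$angles[2],
                       transform$angles[3])
  out <- sweep(p, 2, transform$center) %*% t(R)
  out <- sweep(out, 2, transform$center + transform$translation, "+")
  if (single) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' Returns the transform mapping `T(p)` back to `p`, expressed with the same
#' rotation center.
#'
#' @inheritParams apply_transform
#' @return A function-free closed form: a list with the inverse rotation
#'   matrix and offset, of class `rigid_transform3d_matrix`, usable by
#'   [resample()] and [apply_transform()] via its own method. For parameter
#'   reporting the 6-parameter form of the inverse is generally not unique in
#'   angle parametrization, so the matrix form is returned.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform3d"))
  R <- rotation_matrix(transform$angles[1], transform$angles[2],
                       transform$angles[3])
  # forward: q = R (p - c) + c + t  =>  p = R^T (q - c - t) + c
  matrix_transform(t(R), offset = as.numeric(
    transform$center - t(R) %*% (transform$center + transform$translation)))
}

# Affine convenience form q = R p + offset (center folded in).
matrix_transform <- function(R, offset) {
  structure(list(R = R, offset = as.numeric(offset)),
            class = "rigid_transform3d_matrix")
}

# Internal: any transform -> (R, offset) pair.
as_matrix_form <- function(transform) {
  if (inherits(transform, "rigid_transform3d_matrix")) {
    return(transform)
  }
  R <- rotation_matrix(transform$angles[1], transform$angles[2],
                       transform$angles[3])
  matrix_transform(R, offset = as.numeric(
    transform$center + transform$translation - R %*% transform$center))
}

#' 4x4 homogeneous matrix form of a rigid transform
#'
#' @inheritParams apply_transform
#' @return A 4x4 matrix `A` with `A %*% c(p, 1) = c(T(p), 1)`.
#' @export
transform_matrix <- function(transform) {
  m <- as_matrix_form(transform)
  rbind(cbind(m$R, m$offset), c(0, 0, 0, 1))
}

apply_matrix_form <- function(m, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  out <- p %*% t(m$R)
  out <- sweep(out, 2, m$offset, "+")
  if (single) as.numeric(out) else out
}

#' Mean landmark error between two transforms
#'
#' The fiducial evaluation measure: the mean Euclidean distance, in mm,
#' between the images of a set of landmark points under an estimated
#' transform and under a gold-standard transform,
#' `e = mean_i || T_est(x_i) - T_golden(x_i) ||`.
#'
#' @param t_est,t_golden Rigid transforms ([rigid_transform()] or the matrix
#'   form from [invert_transform()]).
#' @param landmarks An `n x 3` matrix (or data frame) of world points in mm;
#'   gold-standard protocols typically use 8.
#' @return Mean distance in mm.
#' @examples
#' pts <- matrix(rnorm(24, sd = 50), ncol = 3)
#' landmark_error(rigid_transform(translation = c(2, 0, 0)),
#'                pts, rigid_transform())
#' @export
landmark_error <- function(t_est, landmarks, t_golden) {
  lm <- as.matrix(landmarks)
  if (nrow(lm) < 1L) stop("Need at least one landmark pair.", call. = FALSE)
  if (ncol(lm) != 3L) stop("Landmarks must be n x 3 world points.", call. = FALSE)
  a <- apply_matrix_form(as_matrix_form(t_est), lm)
  b <- apply_matrix_form(as_matrix_form(t_golden), lm)
  mean(sqrt(rowSums((a - b)^2)))
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Writes the 6-parameter record (angles in degrees, translation and center
#' in mm) together with the 4x4 matrix form.
#'
#' @param transform A [rigid_transform()].
#' @param path File path to write to / read from.
#' @return `write_transform_json()` returns `path` invisibly;
#'   `read_transform_json()` returns the `rigid_transform3d`.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform3d"))
  rec <- list(angles_deg = transform$angles,
              translation_mm = transform$translation,
              center_mm = transform$center,
              matrix = transform_matrix(transform))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(angles = as.numeric(rec$angles_deg),
                  translation = as.numeric(rec$translation_mm),
                  center = as.numeric(rec$center_mm))
}
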