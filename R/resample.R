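#' Resample a moving volume onto a reference grid
#'
#' Backward (pull) warping: every voxel center of the reference grid is
#' mapped through `transform` into the moving volume's world space and the
#' moving image is interpolated trilinearly there. Coordinates that land
#' outside the moving volume take `fill`, and the returned volume carries a
#' validity `mask` flagging in-field voxels so downstream similarity metrics
#' can exclude the filled ones. All mapping happens in world space, so
#' differing spacings and origins between the two grids are respected.
#'
#' @param moving The [volume3d()] to be resampled.
#' @param transform A [rigid_transform()] (or inverse matrix form) mapping
#'   reference-space world coordinates into moving-space world coordinates.
#' @param reference The [volume3d()] whose grid the output lives on.
#' @param fill Intensity assigned outside the moving field of view.
#' @return A [volume3d()] on the reference grid, with `mask` set.
#' @examples
#' v <- volume3d(array(stats::runif(8 * 8 * 4), c(8, 8, 4)))
#' out <- resample(v, rigid_transform(), v)
#' max(abs(out$data - v$data))
#' @export
resample <- function(moving, transform, reference, fill = 0) {
  stopifnot(inherits(moving, "volume3d"), inherits(reference, "volume3d"))
  m <- as_matrix_form(transform)
  world <- voxel_world_coordinates(reference)
  mapped <- apply_matrix_form(m, world)
  # world -> continuous 1-based voxel index in the moving grid
  idx <- sweep(sweep(mapped, 2, moving$origin), 2, moving$spacing, "/") + 1
  res <- trilinear_sample(as.numeric(moving$data), dim(moving$data), idx, fill)
  d <- dim(reference$data)
  volume3d(array(res$values, dim = d), spacing = reference$spacing,
           origin = reference$origin, mask = array(res$inside, dim = d))
}
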