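#' Apply a spatial transform to physical points
#'
#' Accepts `NULL` (identity), a [rigid_transform], a [displacement_field],
#' a function of an N x 3 matrix, or a list of these (applied left to right:
#' the point is pushed through the first element, then the second, ...).
#'
#' @param transform transform specification (see Details).
#' @param pts N x 3 matrix of physical mm points.
#' @return N x 3 matrix of transformed points.
#' @export
transform_points <- function(transform, pts) {
  if (is.null(transform)) return(pts)
  if (inherits(transform, "rigid_transform")) return(apply_rigid(transform, pts))
  if (inherits(transform, "displacement_field")) return(pts + disp_at(transform, pts))
  if (is.function(transform)) return(transform(pts))
  if (is.list(transform))
    return(Reduce(function(p, tf) transform_points(tf, p), transform, pts))
  stop("unsupported transform type: ", paste(class(transform), collapse = "/"))
}

.is_identity_rigid <- function(tf, tol = 1e-12) {
  inherits(tf, "rigid_transform") &&
    max(abs(tf$angles)) <= tol && max(abs(tf$translation)) <= tol
}

#' Resample a volume onto a target grid
#'
#' Pull/backward warping: each target-grid point is mapped through
#' `transform` into the moving image's space and the moving image is
#' interpolated there.  Points that map outside the moving image receive
#' `fill`.
#'
#' @param vol moving [image_volume].
#' @param target target [image_grid] (defaults to the volume's own grid).
#' @param transform `NULL`, [rigid_transform], [displacement_field], function,
#'   or list of these (see [transform_points]).
#' @param interpolation `"linear"` (intensities) or `"nearest"` (labels).
#' @param fill scalar for out-of-support points; defaults to -1000 for HU
#'   volumes and 0 otherwise.
#' @return [image_volume] on `target`.
#' @export
resample <- function(vol, target = vol$grid, transform = NULL,
                     interpolation = c("linear", "nearest"),
                     fill = default_fill(vol)) {
  interpolation <- match.arg(interpolation)
  if (inherits(transform, "rigid_transform") &&
      any(!is.finite(c(transform$angles, transform$translation, transform$center))))
    stop("non-finite transform parameters")
  if (.is_identity_rigid(transform)) transform <- NULL
  if (is.null(transform) && grid_equal(target, vol$grid)) return(vol)
  pts <- grid_points(target)
  mpts <- transform_points(transform, pts)
  idx <- .p2v(mpts, vol$grid)
  vals <- interp3_cpp(vol$values, dim(vol$values), idx,
                      if (interpolation == "linear") 1L else 0L, fill)
  out <- vol
  out$values <- array(vals, target$size)
  out$grid <- target
  out
}

# Warp a binary mask (logical array on source_grid) onto target_grid:
# linear interpolation of the 0/1 field thresholded at 0.5, ties inside.
resample_mask <- function(mask, source_grid, target_grid = source_grid,
                          transform = NULL) {
  if (.is_identity_rigid(transform)) transform <- NULL
  if (is.null(transform) && grid_equal(target_grid, source_grid)) return(mask)
  pts <- grid_points(target_grid)
  mpts <- transform_points(transform, pts)
  idx <- .p2v(mpts, source_grid)
  vals <- interp3_cpp(as.double(mask), dim(mask), idx, 1L, 0)
  array(vals >= 0.5, target_grid$size)
}
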