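#' Create a rigid transform
#'
#' Six-parameter rigid transform: three rotation angles (radians, about the
#' x, y, z axes, applied in that order) and a translation, with an explicit
#' rotation center.  Transforms map *fixed*-image physical points to
#' *moving*-image physical points (pull/backward warping) throughout the
#' package: `T(x) = R (x - center) + center + translation`.
#'
#' @param angles radians triple, each in (-pi, pi].
#' @param translation mm triple.
#' @param center mm triple, rotation center.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  angles <- as.numeric(angles); translation <- as.numeric(translation)
  center <- as.numeric(center)
  if (any(!is.finite(c(angles, translation, center))))
    stop("rigid transform parameters must be finite")
  if (any(angles <= -pi | angles > pi))
    stop("rotation angles must lie in (-pi, pi]")
  structure(list(angles = angles, translation = translation, center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot (%s) deg, trans (%s) mm, center (%s) mm\n",
              paste(signif(x$angles * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 5), collapse = ", "),
              paste(signif(x$center, 5), collapse = ", ")))
  invisible(x)
}

# R = Rz %*% Ry %*% Rx
rotation_matrix <- function(angles) {
  ca <- cos(angles); sa <- sin(angles)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# inverse euler extraction for R = Rz Ry Rx
matrix_to_angles <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c)
}

apply_rigid <- function(tf, pts) {
  R <- rotation_matrix(tf$angles)
  rel <- sweep(pts, 2L, tf$center, `-`)
  out <- rel %*% t(R)
  sweep(out, 2L, tf$center + tf$translation, `+`)
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform].
#' @return The inverse `rigid_transform` (same rotation center).
#' @export
invert_rigid <- function(tf) {
  R <- rotation_matrix(tf$angles)
  rigid_transform(matrix_to_angles(t(R)),
                  translation = as.numeric(-t(R) %*% tf$translation),
                  center = tf$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform mapping `x` to `outer(inner(x))`.
#'
#' @param outer,inner [rigid_transform] objects.
#' @return A `rigid_transform` with the inner transform's center.
#' @export
compose_rigid <- function(outer, inner) {
  Ra <- rotation_matrix(outer$angles)
  Rb <- rotation_matrix(inner$angles)
  Rc <- Ra %*% Rb
  cb <- inner$center
  t_new <- as.numeric(Ra %*% (cb + inner$translation - outer$center)) +
    outer$center + outer$translation - cb
  rigid_transform(matrix_to_angles(Rc), translation = t_new, center = cb)
}

# magnitude of the net rotation (radians)
rotation_angle <- function(tf) {
  R <- rotation_matrix(tf$angles)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}
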