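#' Define an image grid
#'
#' An image grid places a regular voxel lattice in physical space.  Physical
#' coordinates are patient LPS millimetres, voxel indices are 0-based, and a
#' grid position refers to the voxel *center* (so `origin` is the center of
#' voxel `(0,0,0)`).
#'
#' @param size integer triple `(nx, ny, nz)`, all >= 1.
#' @param spacing mm triple, all > 0. A scalar is recycled.
#' @param origin mm triple: physical position of the center of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction-cosine matrix (columns are the
#'   physical directions of the voxel axes).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(size, spacing, origin, direction = diag(3)) {
  size <- as.integer(round(size))
  if (length(size) != 3L || any(size < 1L))
    stop("grid size must be an integer triple with all components >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be a positive mm triple")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("grid origin must be a finite mm triple")
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("grid direction matrix must be orthonormal (to 1e-6)")
  structure(list(size = size, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid %dx%dx%d, spacing %s mm, origin (%s) mm\n",
              x$size[1], x$size[2], x$size[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 5), collapse = ", ")))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  all(a$size == b$size) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Convert voxel indices to physical points
#'
#' @param index 0-based integer triple or N x 3 matrix of voxel indices.
#' @param grid an [image_grid].
#' @return mm point(s): numeric triple or N x 3 matrix.
#' @export
voxel_to_physical <- function(index, grid) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3L)
  for (a in 1:3) {
    bad <- which(idx[, a] < 0 | idx[, a] > grid$size[a] - 1L)
    if (length(bad))
      stop(sprintf("voxel index out of bounds along axis %s (index %d, valid 0..%d)",
                   c("x", "y", "z")[a], idx[bad[1], a], grid$size[a] - 1L))
  }
  p <- .v2p(idx, grid)
  if (is.matrix(index)) p else drop(p)
}

# unchecked continuous version (rows = points)
.v2p <- function(idx, grid) {
  scaled <- sweep(idx, 2L, grid$spacing, `*`)
  out <- scaled %*% t(grid$direction)
  sweep(out, 2L, grid$origin, `+`)
}

#' Convert physical points to voxel indices
#'
#' @param points mm triple or N x 3 matrix.
#' @param grid an [image_grid].
#' @param continuous if `TRUE`, return continuous (fractional) indices;
#'   otherwise round to the nearest voxel.
#' @return 0-based indices, same shape as `points`.
#' @export
physical_to_voxel <- function(points, grid, continuous = FALSE) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  idx <- .p2v(pts, grid)
  if (!continuous) idx <- round(idx)
  if (is.matrix(points)) idx else drop(idx)
}

.p2v <- function(pts, grid) {
  rel <- sweep(pts, 2L, grid$origin, `-`)
  # direction is orthonormal: inverse = transpose
  sweep(rel %*% grid$direction, 2L, grid$spacing, `/`)
}

# all voxel-center physical points, x fastest (matches array layout)
grid_points <- function(grid) {
  n <- grid$size
  idx <- cbind(
    rep.int(seq_len(n[1]) - 1L, n[2] * n[3]),
    rep.int(rep(seq_len(n[2]) - 1L, each = n[1]), n[3]),
    rep(seq_len(n[3]) - 1L, each = n[1] * n[2]))
  .v2p(idx, grid)
}

# physical center of the grid's bounding box
grid_center <- function(grid) {
  drop(.v2p(matrix((grid$size - 1) / 2, ncol = 3L), grid))
}

# physical coordinates along each axis assuming identity-direction use;
# general helper for axis-separable constructions
grid_axis_coords <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$size[a]) - 1) * grid$spacing[a])
}
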