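#' Create a B-spline displacement field
#'
#' A deformation vector field (DVF) parameterized by a cubic B-spline
#' control-point lattice: per-voxel 3D displacement in mm, C2-smooth by
#' construction.  All-zero control displacements give the identity mapping.
#' Like rigid transforms, a DVF maps fixed-image physical points to
#' moving-image physical points: `phi(x) = x + u(x)` (pull convention).
#'
#' @param control_grid [image_grid] of the control-point lattice.
#' @param control_disp numeric array `(n1, n2, n3, 3)` of control-point
#'   displacements in mm.  Defaults to all zero (identity).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(control_grid, control_disp = NULL) {
  n <- control_grid$size
  if (is.null(control_disp)) control_disp <- array(0, c(n, 3L))
  if (!is.array(control_disp) || length(dim(control_disp)) != 4L ||
      !all(dim(control_disp) == c(n, 3L)))
    stop("control_disp must be an (n1, n2, n3, 3) array matching the control grid")
  if (any(!is.finite(control_disp)))
    stop("control displacements must be finite")
  storage.mode(control_disp) <- "double"
  structure(list(control_grid = control_grid, control_disp = control_disp),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %dx%dx%d control points, spacing %s mm, max |c| %.2f mm\n",
              x$control_grid$size[1], x$control_grid$size[2], x$control_grid$size[3],
              paste(signif(x$control_grid$spacing, 4), collapse = "x"),
              max(abs(x$control_disp))))
  invisible(x)
}

#' Evaluate a displacement field at physical points
#'
#' @param df a [displacement_field].
#' @param pts N x 3 matrix (or triple) of physical mm points.
#' @return N x 3 matrix of displacements in mm.
#' @export
disp_at <- function(df, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3L)
  u <- .p2v(pts, df$control_grid)
  bspline_eval_cpp(df$control_disp, df$control_grid$size, u)
}

# Control lattice covering `grid` with `margin` extra control points on every
# side (cubic support needs one; extra rows absorb boundary conditions).
bspline_lattice <- function(grid, spacing_mm, margin = 2L) {
  lo <- .v2p(matrix(c(0, 0, 0), ncol = 3L), grid)
  hi <- .v2p(matrix(grid$size - 1, ncol = 3L), grid)
  pmin <- pmin(lo, hi); pmax <- pmax(lo, hi)
  n <- ceiling((pmax - pmin) / spacing_mm) + 1L + 2L * margin
  origin <- pmin - margin * spacing_mm
  image_grid(as.integer(n), rep(spacing_mm, 3L), as.numeric(origin), diag(3))
}

# Tridiagonal prefilter so the cubic B-spline INTERPOLATES samples given at
# the lattice nodes (mirror end condition), applied separably per axis.
.bs_prefilter_matrix <- function(n) {
  if (n == 1L) return(matrix(1))
  A <- diag(4 / 6, n)
  for (i in seq_len(n - 1)) { A[i, i + 1] <- 1 / 6; A[i + 1, i] <- 1 / 6 }
  A[1, 2] <- 2 / 6
  A[n, n - 1] <- 2 / 6
  A
}

#' Fit a displacement field that interpolates sampled displacements
#'
#' Samples the supplied field at the control lattice nodes and solves the
#' separable cubic B-spline prefilter so the resulting dense field
#' interpolates those samples exactly at the nodes.
#'
#' @param fun function mapping an N x 3 matrix of physical points to an
#'   N x 3 matrix of mm displacements, or an `(n1,n2,n3,3)` array of samples
#'   at the lattice nodes.
#' @param control_grid [image_grid] of the control lattice.
#' @return A [displacement_field].
#' @export
fit_displacement_field <- function(fun, control_grid) {
  n <- control_grid$size
  if (is.function(fun)) {
    samples <- array(fun(grid_points(control_grid)), c(n, 3L))
  } else samples <- fun
  coef <- samples
  for (axis in 1:3) {
    A <- .bs_prefilter_matrix(n[axis])
    perm <- c(axis, setdiff(1:4, axis))
    x <- aperm(coef, perm)
    dm <- dim(x)
    x <- matrix(x, nrow = dm[1])
    x <- solve(A, x)
    coef <- aperm(array(x, dm), order(perm))
  }
  displacement_field(control_grid, coef)
}

# Minimum Jacobian determinant of phi(x) = x + u(x), finite differences on a
# strided sample of `grid`.
jacobian_min <- function(df, grid, stride = 2L) {
  n <- grid$size
  ix <- seq(0L, n[1] - 1L, by = stride)
  iy <- seq(0L, n[2] - 1L, by = stride)
  iz <- seq(0L, n[3] - 1L, by = stride)
  idx <- as.matrix(expand.grid(ix, iy, iz))
  pts <- .v2p(idx, grid)
  h <- min(grid$spacing)
  J11 <- J22 <- J33 <- rep(1, nrow(pts))
  D <- vector("list", 9)
  for (a in 1:3) {
    e <- c(0, 0, 0); e[a] <- h
    up <- disp_at(df, sweep(pts, 2L, e, `+`))
    dn <- disp_at(df, sweep(pts, 2L, e, `-`))
    g <- (up - dn) / (2 * h)  # d u / d x_a
    for (c in 1:3) D[[(c - 1) * 3 + a]] <- g[, c]
  }
  # J[c,a] = delta_ca + du_c/dx_a
  a11 <- 1 + D[[1]]; a12 <- D[[2]]; a13 <- D[[3]]
  a21 <- D[[4]]; a22 <- 1 + D[[5]]; a23 <- D[[6]]
  a31 <- D[[7]]; a32 <- D[[8]]; a33 <- 1 + D[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  min(det)
}
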