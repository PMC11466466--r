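# Independent oracles used to cross-check the package's fast paths.

# Pure-R trilinear interpolation at continuous 0-based indices; NA outside.
trilin_r <- function(arr, idx) {
  n <- dim(arr)
  N <- nrow(idx)
  out <- rep(NA_real_, N)
  ok <- idx[, 1] >= 0 & idx[, 1] <= n[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= n[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= n[3] - 1
  if (!any(ok)) return(out)
  id <- idx[ok, , drop = FALSE]
  i0 <- pmin(pmax(floor(id[, 1]), 0), max(n[1] - 2, 0))
  j0 <- pmin(pmax(floor(id[, 2]), 0), max(n[2] - 2, 0))
  k0 <- pmin(pmax(floor(id[, 3]), 0), max(n[3] - 2, 0))
  fx <- id[, 1] - i0; fy <- id[, 2] - j0; fz <- id[, 3] - k0
  g <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  i1 <- pmin(i0 + 1, n[1] - 1); j1 <- pmin(j0 + 1, n[2] - 1); k1 <- pmin(k0 + 1, n[3] - 1)
  v <- g(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    g(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
    g(i1, j1, k0) * fx * fy * (1 - fz) +
    g(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    g(i1, j0, k1) * fx * (1 - fy) * fz +
    g(i0, j1, k1) * (1 - fx) * fy * fz +
    g(i1, j1, k1) * fx * fy * fz
  out[ok] <- v
  out
}

# Exhaustive per-voxel gamma pass/fail oracle.  A voxel can only pass via
# offsets within one DTA (the distance term alone exceeds 1 farther out),
# so searching the DTA ball at DTA/10 steps decides pass/fail exactly.
gamma_oracle <- function(ref, ev, spacing, dd_pct, dta, thr_pct) {
  norm <- max(ref)
  tol <- dd_pct / 100 * norm
  thr <- thr_pct / 100 * norm
  s <- seq(-dta, dta, by = dta / 10)
  offs <- as.matrix(expand.grid(s, s, s))
  offs <- offs[rowSums(offs^2) <= dta^2 + 1e-9, , drop = FALSE]
  rr <- rowSums(offs^2) / dta^2
  n <- dim(ref)
  idx <- cbind(rep(0:(n[1] - 1), times = n[2] * n[3]),
               rep(rep(0:(n[2] - 1), each = n[1]), times = n[3]),
               rep(0:(n[3] - 1), each = n[1] * n[2]))
  refv <- as.numeric(ref)
  evaluable <- refv >= thr
  pass <- rep(FALSE, length(refv))
  for (q in seq_len(nrow(offs))) {
    oidx <- offs[q, ] / spacing
    v <- trilin_r(ev, sweep(idx, 2, oidx, `+`))
    g2 <- ((v - refv) / tol)^2 + rr[q]
    pass <- pass | (!is.na(g2) & g2 <= 1)
  }
  list(pass = pass & evaluable, evaluable = evaluable,
       rate = 100 * sum(pass & evaluable) / sum(evaluable))
}

# Brute-force even-odd point-in-polygon over all voxel centers of a grid
# slice (2D; polygon in mm, grid axis-aligned).
pip_oracle <- function(rings, grid, k = 0) {
  ax <- grid$origin[1] + (seq_len(grid$size[1]) - 1) * grid$spacing[1]
  ay <- grid$origin[2] + (seq_len(grid$size[2]) - 1) * grid$spacing[2]
  out <- matrix(FALSE, grid$size[1], grid$size[2])
  for (ix in seq_along(ax)) for (iy in seq_along(ay)) {
    px <- ax[ix]; py <- ay[iy]
    crossings <- 0L
    for (ring in rings) {
      m <- nrow(ring)
      for (e in seq_len(m)) {
        x1 <- ring[e, 1]; y1 <- ring[e, 2]
        f <- if (e == m) 1L else e + 1L
        x2 <- ring[f, 1]; y2 <- ring[f, 2]
        if ((y1 > py) != (y2 > py)) {
          xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
          if (px < xint) crossings <- crossings + 1L
        }
      }
    }
    out[ix, iy] <- (crossings %% 2L) == 1L
  }
  out
}

# Voxel-sorting DVH oracles
d_at_volume_oracle <- function(dose_vals, i) {
  v <- sort(dose_vals, decreasing = TRUE)
  v[max(1L, ceiling(i / 100 * length(v)))]
}
v_at_dose_oracle <- function(dose_vals, d) 100 * mean(dose_vals >= d)

# smooth random 3D field for test volumes
smooth_noise <- function(n, sd = 1, hw = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(adaptcheck:::smooth3_cpp(array(rnorm(prod(n), 0, sd), n),
                                 as.integer(n), as.integer(hw)), n)
}
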