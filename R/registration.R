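#' Registration configuration
#'
#' Defaults follow standard multi-resolution practice: mutual information for
#' CT-CBCT rigid alignment (their intensity relationship is not identity),
#' a 3-level pyramid with shrink factors 4/2/1, and for the B-spline stage a
#' free-form deformation with control spacing halving from 40 mm, optimized
#' by L-BFGS with an analytic gradient and a bending-energy-style smoothness
#' penalty on the control lattice.
#'
#' @param metric `"mutual_information"` (default; robust to the CT-CBCT
#'   intensity relationship), `"correlation"`, or
#'   `"mean_squared_difference"` (same-modality work).
#' @param pyramid_levels number of rigid pyramid levels (shrink `2^(l-1)`).
#' @param max_iterations per-level iteration caps, recycled as needed.
#' @param convergence_tol relative tolerance of the optimizer.
#' @param control_spacing B-spline control spacing (mm) at the finest level.
#' @param smoothness_weight bending-energy weight relative to metric scale.
#' @param bspline_shrink pyramid shrink factors for the deformable stage.
#' @param bspline_iterations per-level L-BFGS iteration caps for the
#'   deformable stage.
#' @param max_samples voxel-sample budget per rigid metric evaluation.
#' @param bspline_max_points voxel-sample budget per deformable objective
#'   evaluation (regular per-axis stride).
#' @param mi_bins joint-histogram bins for mutual information.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(metric = c("mutual_information",
                                           "correlation",
                                           "mean_squared_difference"),
                                pyramid_levels = 3L,
                                max_iterations = c(250L, 150L, 80L),
                                convergence_tol = 1e-7,
                                control_spacing = 20,
                                smoothness_weight = 0.05,
                                bspline_shrink = c(4L, 2L),
                                bspline_iterations = c(30L, 20L),
                                max_samples = 40000L,
                                bspline_max_points = 40000L,
                                mi_bins = 64L) {
  metric <- match.arg(metric)
  if (pyramid_levels < 1L) stop("pyramid_levels must be >= 1")
  cfg <- list(metric = metric, pyramid_levels = as.integer(pyramid_levels),
              max_iterations = max_iterations,
              convergence_tol = convergence_tol,
              control_spacing = control_spacing,
              smoothness_weight = smoothness_weight,
              bspline_shrink = as.integer(bspline_shrink),
              bspline_iterations = as.integer(bspline_iterations),
              max_samples = as.integer(max_samples),
              bspline_max_points = as.integer(bspline_max_points),
              mi_bins = as.integer(mi_bins))
  class(cfg) <- "registration_config"
  cfg
}

#' Prealign a CBCT to the planning CT
#'
#' Isocenter branch: the treatment isocenter coincides with the CBCT scan
#' center, so when the plan provides an isocenter the prealignment is the
#' pure translation mapping the CT point `isocenter` to the CBCT origin
#' `(0,0,0)` - translation `-isocenter` under the pull convention.  Without
#' an isocenter the geometric centers of the two grids are aligned.
#'
#' @param fixed_ct planning [image_volume].
#' @param moving_cbct fraction [image_volume].
#' @param isocenter mm triple from the plan, or `NULL`.
#' @return A [rigid_transform] with attribute `"branch"` set to
#'   `"isocenter"` or `"geometry"`.
#' @export
prealign <- function(fixed_ct, moving_cbct, isocenter = NULL) {
  if (!is.null(isocenter)) {
    tf <- rigid_transform(translation = -as.numeric(isocenter))
    attr(tf, "branch") <- "isocenter"
  } else {
    t <- grid_center(moving_cbct$grid) - grid_center(fixed_ct$grid)
    tf <- rigid_transform(translation = t)
    attr(tf, "branch") <- "geometry"
  }
  tf
}

# re-express a rigid transform about a new rotation center (same mapping)
recenter_rigid <- function(tf, center) {
  R <- rotation_matrix(tf$angles)
  t_new <- as.numeric(R %*% (center - tf$center)) + tf$center +
    tf$translation - center
  rigid_transform(tf$angles, t_new, center)
}

# Deterministic coordinate pattern search: per sweep each parameter is
# probed one step up and down and moves greedily; when a sweep brings no
# improvement all steps halve.  Robust on rough sampled-metric landscapes.
.pattern_search <- function(par, fn, steps, min_steps, max_sweeps = 200L,
                            tol = 0) {
  f0 <- fn(par)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_along(par)) {
      for (s in c(steps[i], -steps[i])) {
        cand <- par
        cand[i] <- cand[i] + s
        fc <- fn(cand)
        if (fc < f0 - tol * abs(f0)) {
          par <- cand; f0 <- fc; improved <- TRUE
          break
        }
      }
    }
    if (!improved) {
      steps <- steps / 2
      if (all(steps < min_steps)) break
    }
  }
  par
}

# negative mutual information (to minimize); fv/mv paired samples
.neg_mi <- function(fv, mv, frange, mrange, bins) {
  fi <- pmin(bins, pmax(1L, 1L + floor((fv - frange[1]) /
                                         diff(frange) * bins)))
  mi <- pmin(bins, pmax(1L, 1L + floor((mv - mrange[1]) /
                                         diff(mrange) * bins)))
  jo <- tabulate(fi + bins * (mi - 1L), bins * bins) / length(fv)
  pf <- tabulate(fi, bins) / length(fv)
  pm <- tabulate(mi, bins) / length(fv)
  jo <- matrix(jo, bins, bins)
  nz <- jo > 0
  outer_p <- outer(pf, pm)
  -sum(jo[nz] * log(jo[nz] / outer_p[nz]))
}

#' Rigid registration of two volumes
#'
#' Six-parameter (three rotations, three translations) multi-resolution
#' registration by direct search of the configured metric, started from
#' `init` (usually [prealign]).  If the optimized transform does not improve
#' the finest-level metric, `init` is returned unchanged.
#'
#' @param fixed,moving [image_volume]s.
#' @param init initial [rigid_transform].
#' @param config [registration_config].
#' @return A [rigid_transform] with attribute `"metric"` (final value).
#' @export
register_rigid <- function(fixed, moving, init = NULL,
                           config = registration_config()) {
  if (is.null(init)) init <- prealign(fixed, moving, NULL)
  center <- grid_center(fixed$grid)
  init_c <- recenter_rigid(init, center)
  shrinks <- 2L^((config$pyramid_levels:1L) - 1L)
  iters <- rep_len(config$max_iterations, config$pyramid_levels)
  par <- c(init_c$angles, init_c$translation)
  mrange <- range(moving$values)
  if (diff(mrange) == 0) mrange <- mrange + c(0, 1)
  level_metric <- function(par, flev, mlev, fpts, fvals, frange) {
    tf <- rigid_transform(par[1:3], par[4:6], center)
    mpts <- apply_rigid(tf, fpts)
    idx <- .p2v(mpts, mlev$grid)
    mv <- interp3_cpp(mlev$values, dim(mlev$values), idx, 1L, NA_real_)
    ok <- !is.na(mv)
    # CBCT voxels outside the scan FOV are exactly at the air fill value and
    # carry no anatomy; drop them from the metric
    if (moving$unit == "HU") ok <- ok & mv > -999.999
    if (mean(ok) < 0.05) return(1e6)
    if (config$metric == "mutual_information")
      .neg_mi(fvals[ok], mv[ok], frange, mrange, config$mi_bins)
    else if (config$metric == "correlation")
      -stats::cor(fvals[ok], mv[ok])
    else mean((mv[ok] - fvals[ok])^2)
  }
  final_ctx <- NULL
  for (l in seq_along(shrinks)) {
    flev <- downsample_volume(fixed, shrinks[l])
    mlev <- downsample_volume(moving, shrinks[l])
    fpts <- grid_points(flev$grid)
    fvals <- as.numeric(flev$values)
    nset <- nrow(fpts)
    if (nset > config$max_samples) {
      stride <- ceiling(nset / config$max_samples)
      keep <- seq(1L, nset, by = stride)
      fpts <- fpts[keep, , drop = FALSE]
      fvals <- fvals[keep]
    }
    frange <- range(flev$values)
    if (diff(frange) == 0) frange <- frange + c(0, 1)
    fn <- function(p) level_metric(p, flev, mlev, fpts, fvals, frange)
    par <- .pattern_search(par, fn,
                           steps = c(rep(1.5 * pi / 180, 3), rep(3, 3)),
                           min_steps = c(rep(0.01 * pi / 180, 3), rep(0.02, 3)),
                           max_sweeps = iters[l], tol = config$convergence_tol)
    final_ctx <- fn
  }
  m_final <- final_ctx(par)
  m_init <- final_ctx(c(init_c$angles, init_c$translation))
  # require a real improvement: sampled-metric noise can "improve" on an
  # already perfect initialization
  if (m_final < m_init - 1e-3 * abs(m_init)) {
    out <- rigid_transform(par[1:3], par[4:6], center)
    attr(out, "metric") <- m_final
  } else {
    out <- init_c
    attr(out, "metric") <- m_init
  }
  attr(out, "branch") <- attr(init, "branch")
  out
}

# ---- B-spline free-form deformation core ------------------------------------

# second-difference operator along one array axis (zero at borders)
.lap_axis <- function(arr, axis) {
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  if (n < 3L) return(out)
  idx_mid <- lapply(seq_along(d), function(a) seq_len(d[a]))
  idx_up <- idx_lo <- idx_mid
  idx_mid[[axis]] <- 2:(n - 1)
  idx_up[[axis]] <- 3:n
  idx_lo[[axis]] <- 1:(n - 2)
  mid <- do.call(`[`, c(list(arr), idx_mid))
  up <- do.call(`[`, c(list(arr), idx_up))
  lo <- do.call(`[`, c(list(arr), idx_lo))
  out <- do.call(`[<-`, c(list(out), idx_mid, list(up - 2 * mid + lo)))
  out
}

.smooth_penalty <- function(coef) {
  val <- 0
  grad <- array(0, dim(coef))
  n <- prod(dim(coef))
  for (axis in 1:3) {
    L <- .lap_axis(coef, axis)
    val <- val + sum(L^2) / n
    grad <- grad + 2 * .lap_axis(L, axis) / n
  }
  list(value = val, grad = grad)
}

# Multi-channel SSD B-spline registration on a shared grid.  `channels` is a
# list of lists with fixed/moving 3D arrays and a fill value; all on `grid`.
.ffd_register <- function(channels, grid, config,
                          ctrl_spacings = NULL, iters = NULL,
                          lambda = NULL) {
  shrinks <- config$bspline_shrink
  if (is.null(ctrl_spacings))
    ctrl_spacings <- config$control_spacing * shrinks / min(shrinks)
  if (is.null(iters)) iters <- config$bspline_iterations
  iters <- rep_len(iters, length(shrinks))
  if (is.null(lambda)) lambda <- config$smoothness_weight
  df <- NULL
  trace_obj <- numeric(0)
  for (l in seq_along(shrinks)) {
    f <- shrinks[l]
    # downsample all channels with one dummy volume for geometry
    geo <- downsample_volume(
      image_volume(array(0, grid$size), grid, unit = "dimensionless",
                   role = "dose"), f)
    lgrid <- geo$grid
    ch <- lapply(channels, function(c0) {
      list(fixed = array(block_mean_cpp(c0$fixed, grid$size, f), lgrid$size),
           moving = array(block_mean_cpp(c0$moving, grid$size, f), lgrid$size),
           fill = c0$fill)
    })
    lattice <- bspline_lattice(lgrid, max(ctrl_spacings[l], 2 * max(lgrid$spacing)))
    coef0 <- if (is.null(df)) array(0, c(lattice$size, 3))
      else fit_displacement_field(function(p) disp_at(df, p), lattice)$control_disp
    pts <- grid_points(lgrid)
    fsel <- NULL
    if (nrow(pts) > config$bspline_max_points) {
      # regular per-axis stride keeps the sample spatially uniform
      sax <- ceiling((nrow(pts) / config$bspline_max_points)^(1 / 3))
      keep <- lapply(lgrid$size, function(n) seq(1L, n, by = sax))
      fsel <- as.matrix(expand.grid(keep))
      fsel <- fsel[, 1] + (fsel[, 2] - 1L) * lgrid$size[1] +
        (fsel[, 3] - 1L) * lgrid$size[1] * lgrid$size[2]
      pts <- pts[fsel, , drop = FALSE]
    }
    cpts <- .p2v(pts, lattice)
    npts <- nrow(pts)
    fvals <- lapply(ch, function(c0) {
      v <- as.numeric(c0$fixed)
      if (is.null(fsel)) v else v[fsel]
    })
    lam <- 0
    cdim <- dim(coef0)
    # value and exact analytic gradient share one pass (cached per point)
    cache <- new.env(parent = emptyenv())
    evalp <- function(parv) {
      if (!is.null(cache$par) && identical(parv, cache$par)) return(cache$res)
      coef <- array(parv, cdim)
      u <- bspline_eval_cpp(coef, lattice$size, cpts)
      widx <- .p2v(pts + u, lgrid)
      # border-replicate sampling keeps the objective continuous at the
      # image boundary (no fill-value jumps)
      for (a in 1:3) widx[, a] <- pmin(pmax(widx[, a], 0), lgrid$size[a] - 1)
      ssd <- 0
      W <- matrix(0, npts, 3)
      for (i in seq_along(ch)) {
        vg <- interp3_vg_cpp(ch[[i]]$moving, lgrid$size, widx, ch[[i]]$fill)
        r <- vg[, 1] - fvals[[i]]
        ssd <- ssd + mean(r^2)
        for (a in 1:3)
          W[, a] <- W[, a] + 2 * r * vg[, 1 + a] / (lgrid$spacing[a] * npts)
      }
      pen <- .smooth_penalty(coef)
      gc_ <- bspline_adjoint_cpp(lattice$size, cpts, W)
      res <- list(value = ssd + lam * pen$value,
                  grad = as.numeric(gc_) + lam * as.numeric(pen$grad))
      cache$par <- parv
      cache$res <- res
      res
    }
    obj <- function(parv) evalp(parv)$value
    grd <- function(parv) evalp(parv)$grad
    # smoothness weight relative to the residual scale at this level's start
    ssd0 <- obj(as.numeric(coef0))
    if (ssd0 <= 1e-12 * max(1, mean(fvals[[1]]^2))) {
      # already converged to numerical precision (identical images)
      df <- displacement_field(lattice, coef0)
      trace_obj <- c(trace_obj, ssd0)
      next
    }
    lam <- lambda * ssd0
    cache$par <- NULL
    bound <- 0.39 * lattice$spacing[1]  # stays clear of the folding regime
    fit <- optim(as.numeric(coef0), obj, grd, method = "L-BFGS-B",
                 lower = pmin(as.numeric(coef0), -bound),
                 upper = pmax(as.numeric(coef0), bound),
                 control = list(maxit = iters[l], factr = 1e7))
    coef_l <- array(fit$par, cdim)
    df_l <- displacement_field(lattice, coef_l)
    if (jacobian_min(df_l, lgrid, stride = 2L) <= 0) {
      warning("deformation field folds; increasing smoothness and retrying once")
      lam_old <- lam
      lam <- lam * 10
      fit2 <- optim(as.numeric(coef0), obj, grd, method = "L-BFGS-B",
                    lower = pmin(as.numeric(coef0), -bound),
                    upper = pmax(as.numeric(coef0), bound),
                    control = list(maxit = iters[l], factr = 1e7))
      lam <- lam_old
      df2 <- displacement_field(lattice, array(fit2$par, cdim))
      if (jacobian_min(df2, lgrid, stride = 2L) > 0) df_l <- df2
    }
    df <- df_l
    trace_obj <- c(trace_obj, fit$value)
  }
  attr(df, "objective") <- trace_obj
  df
}

# central-difference gradient arrays (value per mm) of a 3D array
.image_gradient <- function(vals, grid) {
  d <- dim(vals)
  out <- list()
  for (a in 1:3) {
    g <- array(0, d)
    n <- d[a]
    if (n >= 3) {
      idx <- lapply(d, seq_len)
      iu <- il <- im <- idx
      im[[a]] <- 2:(n - 1); iu[[a]] <- 3:n; il[[a]] <- 1:(n - 2)
      diffv <- (do.call(`[`, c(list(vals), iu)) -
                  do.call(`[`, c(list(vals), il))) / (2 * grid$spacing[a])
      g <- do.call(`[<-`, c(list(g), im, list(diffv)))
    }
    out[[a]] <- g
  }
  out
}

#' Deformable B-spline registration
#'
#' Multi-resolution free-form deformation minimizing the sum of squared
#' intensity differences plus a smoothness penalty, with analytic gradients.
#' The returned field maps fixed-image physical points to moving-image
#' points (pull convention) and is defined over the fixed grid.
#'
#' @param fixed,moving [image_volume]s on comparable grids.
#' @param init_rigid optional [rigid_transform]; when given, `moving` is
#'   first resampled into the fixed grid through it.
#' @param config [registration_config].
#' @return A [displacement_field] with attribute `"objective"` (per-level
#'   final objective values).
#' @export
register_bspline <- function(fixed, moving, init_rigid = NULL,
                             config = registration_config()) {
  if (!is.null(init_rigid))
    moving <- resample(moving, fixed$grid, init_rigid)
  if (!grid_equal(fixed$grid, moving$grid))
    moving <- resample(moving, fixed$grid)
  fillv <- default_fill(moving)
  channels <- list(list(fixed = fixed$values, moving = moving$values,
                        fill = fillv))
  .ffd_register(channels, fixed$grid, config)
}

#' Warp an image through a displacement field
#'
#' @param vol [image_volume].
#' @param dvf [displacement_field] covering the volume's grid.
#' @param target output [image_grid] (defaults to the volume's grid).
#' @return Warped [image_volume].
#' @export
warp_image <- function(vol, dvf, target = vol$grid) {
  resample(vol, target, dvf)
}

#' Propagate a binary mask through a displacement field
#'
#' The 0/1 field is warped with linear interpolation and thresholded at 0.5
#' (ties count as inside).
#'
#' @param mask logical 3D array.
#' @param grid the mask's [image_grid].
#' @param dvf [displacement_field] (or any transform accepted by
#'   [transform_points]).
#' @param target output [image_grid].
#' @return Logical 3D array on `target`.
#' @export
propagate_mask <- function(mask, grid, dvf, target = grid) {
  resample_mask(mask, grid, target, dvf)
}
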