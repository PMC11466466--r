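# Deterministic dose recomputation engine: primary exponential attenuation
# along Siddon radiological depth, inverse-square divergence, and an
# error-function lateral penumbra per rectangular beam aperture.  This is a
# fast analytic photon-beam model: it makes anatomy changes (bladder
# filling, body contour, target displacement) move DVH metrics in
# physically sensible directions, which is what the evaluation layer needs.

#' Convert HU to mass density
#'
#' Piecewise-linear table (-1000 -> 0.0, 0 -> 1.0, 1000 -> 1.6,
#' 3000 -> 2.9) g/cm^3, clamped outside.
#'
#' @param ct [image_volume] in HU.
#' @return [image_volume] with role `"density"` (g/cm^3).
#' @export
hu_to_density <- function(ct) {
  if (ct$unit != "HU") stop("hu_to_density expects an HU volume")
  kx <- c(-1000, 0, 1000, 3000)
  ky <- c(0, 1, 1.6, 2.9)
  vals <- array(approx(kx, ky, xout = as.numeric(ct$values), rule = 2)$y,
                ct$grid$size)
  out <- image_volume(vals, ct$grid, unit = "dimensionless", role = "density")
  out
}

#' Radiological depth along a ray
#'
#' Exact Siddon line integral of density times geometric length over the
#' voxels traversed from `source` to `target` (g/cm^2).  Segments outside
#' the grid contribute nothing.
#'
#' @param density [image_volume] from [hu_to_density].
#' @param source,target mm points (or `target` as an N x 3 matrix).
#' @return g/cm^2 value(s).
#' @export
radiological_depth <- function(density, source, target) {
  tgt <- if (is.matrix(target)) target else matrix(target, ncol = 3)
  src_idx <- drop(.p2v(matrix(source, 1), density$grid))
  tgt_idx <- .p2v(tgt, density$grid)
  out <- ray_depth_cpp(density$values, density$grid$size,
                       density$grid$spacing, src_idx, tgt_idx)
  if (is.matrix(target)) out else out[1]
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Recompute the plan dose on an anatomy image
#'
#' For each beam the source sits at the source-axis distance from the
#' isocenter along the gantry direction (gantry 0 = anterior, rotating
#' about the patient z axis).  The voxel dose contribution is
#' `weight * exp(-mu_per_rho * radiological_depth) * (SAD / r)^2 * penumbra`,
#' with an error-function aperture edge (sigma 3 mm at the isocenter plane,
#' scaled by divergence).  Beam doses are summed and the plan is normalized
#' at full-course scale.
#'
#' Normalization modes: `"isocenter"` scales the mean dose of a 1 cm sphere
#' at the isocenter to the prescription; `"ptv_d98"` scales D98% of the PTV
#' to 100.2% of the prescription (clinical-style coverage normalization,
#' used for phantom reference plans); `"plan"` reuses the frozen
#' `output_factor` of the plan (same-monitor-unit recomputation on new
#' anatomy - the mode the adaptive check uses).
#'
#' @param ct anatomy [image_volume] in HU.
#' @param plan [plan_info] with at least one beam and an isocenter.
#' @param grid dose [image_grid] (defaults to the CT grid).
#' @param normalization `"isocenter"`, `"ptv_d98"` or `"plan"`.
#' @param ptv_mask logical array on `grid`, required for `"ptv_d98"`.
#' @param mu_per_rho effective attenuation coefficient (cm^2/g).
#' @param sigma_mm penumbra sigma at the isocenter plane.
#' @return [dose_volume] with attribute `"output_factor"`.
#' @export
compute_plan_dose <- function(ct, plan, grid = ct$grid,
                              normalization = c("isocenter", "ptv_d98", "plan"),
                              ptv_mask = NULL, mu_per_rho = 0.05,
                              sigma_mm = 3) {
  normalization <- match.arg(normalization)
  if (!length(plan$beams)) stop("plan has no beams")
  if (is.null(plan$isocenter)) stop("plan has no isocenter")
  iso <- plan$isocenter
  lo <- drop(.v2p(matrix(c(0, 0, 0), 1), ct$grid))
  hi <- drop(.v2p(matrix(ct$grid$size - 1, 1), ct$grid))
  if (any(iso < pmin(lo, hi) - 1e-6) || any(iso > pmax(lo, hi) + 1e-6))
    stop("isocenter lies outside the anatomy image")
  w_tot <- sum(vapply(plan$beams, function(b) as.numeric(b$weight %||% 1),
                      numeric(1)))
  if (w_tot <= 0) stop("total beam weight is zero")
  dens <- hu_to_density(if (grid_equal(grid, ct$grid)) ct else resample(ct, grid))
  pts <- grid_points(grid)
  dose <- numeric(nrow(pts))
  for (b in plan$beams) {
    th <- b$gantry_angle * pi / 180
    sdir <- c(sin(th), -cos(th), 0)          # isocenter -> source
    src <- iso + b$source_axis_distance * sdir
    axis <- -sdir                            # source -> isocenter
    u <- c(cos(th), sin(th), 0)
    vvec <- c(0, 0, 1)
    rel <- sweep(pts, 2L, src, `-`)
    proj <- rel %*% axis
    ok0 <- proj > 0.1 * b$source_axis_distance
    scale <- b$source_axis_distance / proj
    ub <- (rel %*% u) * scale
    vb <- (rel[, 3]) * scale
    sig <- sigma_mm * proj / b$source_axis_distance
    hx <- b$aperture$half_x; hy <- b$aperture$half_y
    Fu <- 0.5 * (erf((hx - ub) / (sig * sqrt(2))) +
                   erf((hx + ub) / (sig * sqrt(2))))
    Fv <- 0.5 * (erf((hy - vb) / (sig * sqrt(2))) +
                   erf((hy + vb) / (sig * sqrt(2))))
    Fp <- as.numeric(Fu * Fv)
    cand <- which(ok0 & Fp > 1e-7)
    if (!length(cand)) next
    depth <- ray_depth_cpp(dens$values, grid$size, grid$spacing,
                           drop(.p2v(matrix(src, 1), grid)),
                           .p2v(pts[cand, , drop = FALSE], grid))
    r2 <- rowSums(rel[cand, , drop = FALSE]^2)
    dose[cand] <- dose[cand] +
      as.numeric(b$weight %||% 1) * exp(-mu_per_rho * depth) *
      (b$source_axis_distance^2 / r2) * Fp[cand]
  }
  rx <- plan$prescription_dose
  factor <- switch(normalization,
    isocenter = {
      sphere <- rowSums(sweep(pts, 2L, iso, `-`)^2) <= 10^2
      m <- mean(dose[sphere])
      if (!is.finite(m) || m <= 0) stop("no dose at the isocenter; cannot normalize")
      rx / m
    },
    ptv_d98 = {
      if (is.null(ptv_mask)) stop("ptv_d98 normalization requires ptv_mask")
      d98 <- quantile(dose[as.logical(ptv_mask)], 0.02, names = FALSE, type = 7)
      if (!is.finite(d98) || d98 <= 0) stop("PTV receives no dose; cannot normalize")
      1.002 * rx / d98
    },
    plan = {
      if (is.null(plan$output_factor))
        stop("plan normalization requires a frozen output_factor ",
             "(compute the reference dose first)")
      plan$output_factor
    })
  out <- dose_volume(array(dose * factor, grid$size), grid, prescription = rx)
  attr(out, "output_factor") <- factor
  out
}
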