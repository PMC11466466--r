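# Combined-CT construction: HU-calibrate the CBCT against the rigidly
# aligned planning CT (synthetic-CT stand-in), then splice the calibrated
# CBCT into the planning CT over the CBCT field of view.

#' Calibrate CBCT intensities against the aligned planning CT
#'
#' Deterministic stand-in for a learned synthetic-CT generator: a monotone
#' piecewise-linear HU mapping with 16 knots over [-1000, 1500] is fitted on
#' voxel pairs inside the CBCT field of view.  Each knot's output is the
#' knot position plus the median CT-minus-CBCT offset of the pairs nearest
#' that knot (robust to noise; exactly identity when the images agree),
#' isotonically corrected so the mapping never reorders two HU values.  Any
#' HU-faithful learned generator can be substituted upstream; downstream
#' stages only require CT-like voxel values.
#'
#' @param cbct fraction [image_volume] (with optional `"fov"` attribute;
#'   defaults to voxels above -1000).
#' @param ct_aligned planning CT resampled onto the CBCT grid by the rigid
#'   transform.
#' @param knots number of calibration knots.
#' @param hu_range knot range.
#' @param min_pairs_per_knot minimum pairs to estimate a knot offset.
#' @return [image_volume] with role `"sct"` and attribute `"mapping"`
#'   (data.frame of knot inputs/outputs); the `"fov"` attribute is carried.
#' @export
calibrate_hu <- function(cbct, ct_aligned, knots = 16L,
                         hu_range = c(-1000, 1500), min_pairs_per_knot = 30L) {
  if (!grid_equal(cbct$grid, ct_aligned$grid, tol = 1e-6))
    stop("ct_aligned must be resampled onto the CBCT grid")
  fov <- attr(cbct, "fov")
  if (is.null(fov)) fov <- cbct$values > -1000
  if (sum(fov) < 1000)
    stop("fewer than 1000 valid voxel pairs inside the FOV; cannot calibrate")
  # fit only on low-gradient voxels: edge voxels pair partial-volume values
  # across tissue boundaries and poison the per-knot medians
  gr <- .image_gradient(ct_aligned$values, ct_aligned$grid)
  gmag <- sqrt(gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2)
  flat <- fov & gmag < 15
  if (sum(flat) < 1000) flat <- fov
  cb <- cbct$values[flat]
  ct <- ct_aligned$values[flat]
  # intensity errors are bounded; pairs with huge offsets are anatomy
  # mismatches (organs that moved between scan and plan), not calibration
  # signal
  d0 <- ct - cb
  keep <- abs(d0 - median(d0)) <= 150
  if (sum(keep) >= 1000) {
    cb <- cb[keep]; ct <- ct[keep]
    flat[flat] <- keep
  }
  kx <- seq(hu_range[1], hu_range[2], length.out = knots)
  bw <- diff(kx[1:2])
  bin <- pmin(knots, pmax(1L, 1L + as.integer(round((cb - kx[1]) / bw))))
  offs <- rep(NA_real_, knots)
  minp <- max(min_pairs_per_knot, 0.002 * length(cb))
  for (j in seq_len(knots)) {
    sel <- bin == j
    if (sum(sel) >= minp) {
      d <- ct[sel] - cb[sel]
      # a consistent plateau has a tight offset spread; mixed partial-volume
      # bins do not and would poison the map
      if (stats::mad(d) <= 60) offs[j] <- median(d)
    }
  }
  if (all(is.na(offs))) stop("no calibration knot has enough voxel pairs")
  if (any(is.na(offs))) {
    ok <- which(!is.na(offs))
    offs <- approx(kx[ok], offs[ok], xout = kx, rule = 2)$y
  }
  ky <- kx + offs
  iso <- isoreg(kx, ky)
  ky <- iso$yf
  # residual radial bias-field (cupping) correction about the scan axis:
  # a global HU map cannot remove a spatially varying offset, so the median
  # CT-minus-mapped residual on flat voxels is estimated per radius bin
  co <- .coord_arrays(cbct$grid)
  radius <- sqrt(co$x^2 + co$y^2)
  rad <- radius[flat]
  mapped_flat <- approx(kx, ky, xout = cb, rule = 2)$y
  nb <- 12L
  redge <- seq(0, max(rad) + 1e-6, length.out = nb + 1L)
  rb <- pmin(nb, pmax(1L, findInterval(rad, redge)))
  rmid <- (redge[-1] + redge[-(nb + 1L)]) / 2
  rcorr <- rep(NA_real_, nb)
  for (j in seq_len(nb)) {
    sel <- rb == j
    if (sum(sel) >= min_pairs_per_knot)
      rcorr[j] <- median(ct[sel] - mapped_flat[sel])
  }
  vals <- cbct$values
  mapped <- approx(kx, ky, xout = cbct$values[fov], rule = 2)$y
  if (any(!is.na(rcorr))) {
    ok <- which(!is.na(rcorr))
    rcorr <- approx(rmid[ok], rcorr[ok], xout = rmid, rule = 2)$y
    mapped <- mapped + approx(rmid, rcorr, xout = radius[fov], rule = 2)$y
  }
  vals[fov] <- mapped
  out <- image_volume(vals, cbct$grid, unit = "HU", role = "sct")
  attr(out, "fov") <- fov
  attr(out, "mapping") <- data.frame(input = kx, output = ky)
  out
}

#' Build the combined CT by cropping and splicing
#'
#' On the planning-CT grid: voxels mapping inside the CBCT field of view
#' take the calibrated sCT value, voxels outside keep the planning CT value,
#' with a cosine blend ramp (default 5 mm) just inside the FOV seam to avoid
#' dose-gradient artifacts.  The planning grid is kept so the original plan
#' geometry is preserved for dose recomputation.
#'
#' @param planning_ct planning [image_volume].
#' @param cbct_or_sct calibrated CBCT ([calibrate_hu] output) or raw CBCT.
#' @param rigid [rigid_transform] mapping planning-CT points to CBCT points.
#' @param blend_mm blend ramp width.
#' @return [image_volume] with role `"combined_ct"` and attributes `"fov"`
#'   (resampled FOV mask), `"interior"` (voxels taking the pure sCT value)
#'   and `"blend"` (the blend weight array).
#' @export
build_combined_ct <- function(planning_ct, cbct_or_sct, rigid, blend_mm = 5) {
  fov <- attr(cbct_or_sct, "fov")
  if (is.null(fov)) fov <- cbct_or_sct$values > -1000
  s_res <- resample(cbct_or_sct, planning_ct$grid, rigid, fill = -1000)
  fov_vol <- image_volume(array(as.double(fov), cbct_or_sct$grid$size),
                          cbct_or_sct$grid, unit = "dimensionless", role = "cbct")
  fov_res <- resample(fov_vol, planning_ct$grid, rigid, fill = 0)$values >= 0.999
  if (!any(fov_res))
    stop("empty overlap between the CBCT field of view and the planning CT")
  d <- mask_distance_to(!fov_res, planning_ct$grid)  # mm to the FOV exterior
  w <- array(0, planning_ct$grid$size)
  inside <- fov_res
  ramp <- inside & d < blend_mm
  w[inside] <- 1
  w[ramp] <- 0.5 - 0.5 * cos(pi * d[ramp] / blend_mm)
  vals <- planning_ct$values
  mix <- w > 0
  vals[mix] <- w[mix] * s_res$values[mix] + (1 - w[mix]) * planning_ct$values[mix]
  out <- image_volume(vals, planning_ct$grid, unit = "HU", role = "combined_ct")
  attr(out, "fov") <- fov_res
  attr(out, "interior") <- inside & !ramp
  attr(out, "blend") <- w
  out
}

#' Produce the deformed planning CT used for dose calculation
#'
#' Pull-warps the planning CT through the intensity DIR field (fixed =
#' combined CT, moving = planning CT) onto the combined-CT grid.  A folding
#' field only triggers a warning: the dose image tolerates local overlap.
#'
#' @param planning_ct planning [image_volume].
#' @param dvf_dir [displacement_field] from [register_bspline].
#' @param target output grid (defaults to the planning grid, on which the
#'   combined CT lives).
#' @return [image_volume] with role `"dpct"`.
#' @export
make_deformed_ct <- function(planning_ct, dvf_dir,
                             target = planning_ct$grid) {
  if (jacobian_min(dvf_dir, target, stride = 4L) <= 0)
    warning("DIR field folds locally; proceeding (dose image is tolerant)")
  out <- resample(planning_ct, target, dvf_dir)
  out$role <- "dpct"
  out
}
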