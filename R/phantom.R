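#' Parameters for the synthetic pelvis phantom
#'
#' Defaults define the package's standard validation conditions: a 96^3 voxel
#' pelvis at 2.5 mm spacing, fraction-day bladder filling (+25% volume) and
#' rectal emptying (-15%), a smooth random residual deformation of up to
#' 5 mm, a setup error of up to 5 mm / 2 degrees per axis, and CBCT
#' degradation (cylindrical field of view, cupping, HU shift, noise) typical
#' of clinical cone-beam imaging.  Organ geometry scales with the grid's
#' physical extent so smaller grids still hold a complete pelvis.
#'
#' @param size integer triple of voxels.
#' @param spacing_mm isotropic voxel spacing.
#' @param bladder_scale,rectum_scale fraction-day organ volume factors.
#' @param deform_mm peak random residual deformation (mm); 0 disables.
#' @param rigid_mm,rigid_deg per-axis setup error ranges (uniform draws).
#' @param target_shift_mm rigid-like local displacement of the CTV region in
#'   mm, emulating cervix/uterus motion with bladder filling; set beyond the
#'   PTV margin to emulate fractions that need adaptation.  0 disables.
#' @param target_shift_dir direction of the target shift (normalized
#'   internally); default posterior-superior.
#' @param ptv_margin_mm CTV-to-PTV expansion.
#' @param ctrl_spacing_mm control-point spacing of the ground-truth DVF.
#' @param cupping_hu center-to-edge cupping amplitude inside the CBCT FOV.
#' @param hu_shift global CBCT HU bias.
#' @param noise_sd Gaussian CBCT noise (HU).
#' @param fov_radius_frac CBCT cylinder radius as a fraction of the body's
#'   major semi-axis.
#' @param fov_z_frac CBCT axial coverage as a fraction of the CT extent.
#' @param aperture_margin_mm beam aperture margin beyond the PTV projection.
#' @param mu_per_rho effective linear attenuation per unit density (cm^2/g).
#' @param sad_mm source-axis distance.
#' @param prescription_gy,n_fractions plan prescription (full course).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(size = c(96, 96, 96), spacing_mm = 2.5,
                           bladder_scale = 1.35, rectum_scale = 0.8,
                           deform_mm = 5, rigid_mm = 5, rigid_deg = 2,
                           target_shift_mm = 4,
                           target_shift_dir = c(0, 0.6, 0.8),
                           ptv_margin_mm = 5,
                           ctrl_spacing_mm = 20,
                           cupping_hu = 80, hu_shift = 30, noise_sd = 20,
                           fov_radius_frac = 0.7, fov_z_frac = 0.7,
                           aperture_margin_mm = 10, mu_per_rho = 0.05,
                           sad_mm = 1000, prescription_gy = 45,
                           n_fractions = 25L) {
  p <- as.list(environment())
  class(p) <- "phantom_params"
  p
}

# physical coordinate arrays (identity-direction grids)
.coord_arrays <- function(grid) {
  ax <- grid_axis_coords(grid)
  n <- grid$size
  list(x = array(rep(ax[[1]], times = n[2] * n[3]), n),
       y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), n),
       z = array(rep(ax[[3]], each = n[1] * n[2]), n))
}

.ellipsoid <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

.tube_z <- function(co, center_xy, radius, zlim) {
  ((co$x - center_xy[1])^2 + (co$y - center_xy[2])^2 <= radius^2) &
    co$z >= zlim[1] & co$z <= zlim[2]
}

# Pelvis-like anatomy: nominal mm dimensions defined for a 237.5 mm extent
# and scaled to the actual grid.
.phantom_anatomy <- function(grid, p) {
  ext <- min((grid$size - 1) * grid$spacing)
  s <- ext / 237.5
  if (s < 0.4)
    stop("grid too small for the pelvis anatomy; organs cannot fit without ",
         "overlap - use a larger grid or smaller organs")
  co <- .coord_arrays(grid)
  body_semi <- c(110, 90) * s
  body <- ((co$x / body_semi[1])^2 + (co$y / body_semi[2])^2) <= 1
  ring <- (((co$x / (88 * s))^2 + (co$y / (72 * s))^2) <= 1) &
    (((co$x / (74 * s))^2 + (co$y / (58 * s))^2) > 1) &
    co$z >= -60 * s & co$z <= 35 * s
  fem_l <- .ellipsoid(co, c(72, 8, -18) * s, rep(21 * s, 3))
  fem_r <- .ellipsoid(co, c(-72, 8, -18) * s, rep(21 * s, 3))
  bone <- ring | fem_l | fem_r
  cord <- .tube_z(co, c(0, 50) * s, 5 * s, c(-105, 105) * s)
  rect_c <- c(0, 34, 0) * s; rect_r <- 13 * s; rect_z <- c(-70, 25) * s
  rectum <- .tube_z(co, rect_c[1:2], rect_r, rect_z) & !bone
  blad_c <- c(0, -28, -6) * s; blad_semi <- c(28, 22, 26) * s
  bladder <- .ellipsoid(co, blad_c, blad_semi) & !bone
  ctv_c <- c(0, 3, -5) * s
  ctv <- .ellipsoid(co, ctv_c, c(24, 15, 28) * s) & !bladder & !rectum & !bone
  ptv <- mask_dilate(ctv, grid, p$ptv_margin_mm)
  intestine <- .ellipsoid(co, c(0, -2, 62) * s, c(58, 44, 42) * s) &
    !bladder & !rectum & !bone & !ptv & body
  marrow <- mask_erode(bone, grid, 5)
  masks <- list(skin = body,
                femoral_head_l = fem_l, femoral_head_r = fem_r,
                pelvis = ring, spinal_cord = cord,
                rectum = rectum, small_intestine = intestine,
                bladder = bladder, bone_marrow = marrow,
                CTV = ctv, PTV = ptv)
  roles <- c(skin = "influencer",
             femoral_head_l = "rigid_organ", femoral_head_r = "rigid_organ",
             pelvis = "rigid_organ", spinal_cord = "rigid_organ",
             rectum = "influencer", small_intestine = "influencer",
             bladder = "influencer", bone_marrow = "rigid_organ",
             CTV = "target", PTV = "target")
  list(structures = structure_set(masks, grid, roles),
       scale = s, co = co,
       body_semi = body_semi,
       bladder_center = blad_c, bladder_semi = blad_semi,
       rectum_center = rect_c, rectum_radius = rect_r, rectum_zlim = rect_z,
       ctv_center = ctv_c)
}

.phantom_hu <- function(grid, anat) {
  m <- anat$structures$masks
  s <- anat$scale
  hu <- array(-1000, grid$size)
  hu[m$skin] <- 35
  fat <- m$skin & !mask_erode(m$skin, grid, 12 * s)
  hu[fat] <- -90
  hu[m$small_intestine] <- 25
  hu[m$rectum] <- 30
  hu[m$bladder] <- 15
  hu[m$CTV] <- 45
  hu[m$pelvis | m$femoral_head_l | m$femoral_head_r] <- 700
  hu[m$bone_marrow] <- 160
  hu[m$spinal_cord] <- 40
  array(smooth3_cpp(hu, grid$size, 1L), grid$size)
}

# Radial ellipsoidal rescale field in pull form: phi(x) = c + (x - c) m(rho)
# with m = 1/k inside the scaled boundary (k = volume_scale^(1/3)) relaxing
# to 1 over a cosine ramp of width w (normalized-radius units).
.radial_component <- function(pts, center, semi, vol_scale, ramp_mm) {
  k <- vol_scale^(1 / 3)
  rel <- sweep(pts, 2L, center, `-`)
  rho <- sqrt((rel[, 1] / semi[1])^2 + (rel[, 2] / semi[2])^2 +
                (rel[, 3] / semi[3])^2)
  w <- ramp_mm / mean(semi)
  m <- rep(1, length(rho))
  inner <- rho <= k
  m[inner] <- 1 / k
  mid <- rho > k & rho < k + w
  m[mid] <- 1 + (1 / k - 1) * 0.5 * (1 + cos(pi * (rho[mid] - k) / w))
  rel * (m - 1)
}

# Cylindrical (xy) version for tubular organs, tapered near the tube ends.
.radial_tube_component <- function(pts, center_xy, radius, zlim, vol_scale,
                                   ramp_mm, taper_mm = 15) {
  k <- sqrt(vol_scale)  # area scale in-plane
  relx <- pts[, 1] - center_xy[1]
  rely <- pts[, 2] - center_xy[2]
  rho <- sqrt(relx^2 + rely^2) / radius
  w <- ramp_mm / radius
  m <- rep(1, length(rho))
  inner <- rho <= k
  m[inner] <- 1 / k
  mid <- rho > k & rho < k + w
  m[mid] <- 1 + (1 / k - 1) * 0.5 * (1 + cos(pi * (rho[mid] - k) / w))
  z <- pts[, 3]
  taper <- rep(1, length(z))
  below <- z < zlim[1]; above <- z > zlim[2]
  taper[below] <- pmax(0, 1 - (zlim[1] - z[below]) / taper_mm)
  taper[above] <- pmax(0, 1 - (z[above] - zlim[2]) / taper_mm)
  g <- (m - 1) * taper
  cbind(relx * g, rely * g, 0)
}

# Localized translation field: -shift inside radius r0, cosine decay to 0 by r1.
.shift_component <- function(pts, center, shift_vec, r0, r1) {
  rel <- sweep(pts, 2L, center, `-`)
  r <- sqrt(rowSums(rel^2))
  g <- rep(0, length(r))
  g[r <= r0] <- 1
  mid <- r > r0 & r < r1
  g[mid] <- 0.5 * (1 + cos(pi * (r[mid] - r0) / (r1 - r0)))
  -outer(g, shift_vec)
}

#' Sample a ground-truth deformation field
#'
#' Superposes a smooth random B-spline field with analytic organ components:
#' a radial bladder volume change, a radial rectum volume change and an
#' optional localized target shift.  The analytic components are fitted so
#' the dense field interpolates them at the control lattice nodes.  The
#' field is checked for folding (Jacobian determinant > 0.05 on a dense
#' sample); on failure the random part is damped and resampling is retried
#' up to five times.
#'
#' @param params [phantom_params].
#' @param seed integer seed (only used when called standalone; inside
#'   [generate_case] the case RNG stream is already active).
#' @param grid CT [image_grid] the field should cover.
#' @param anat internal anatomy description; built from `params` when `NULL`.
#' @param use_current_rng draw from the active RNG stream instead of seeding.
#' @return A [displacement_field] (pull convention: fraction space to
#'   planning space).
#' @export
sample_deformation <- function(params, seed = 1L, grid = NULL, anat = NULL,
                               use_current_rng = FALSE) {
  if (is.null(grid)) {
    n <- params$size
    grid <- image_grid(n, params$spacing_mm,
                      -(n - 1) * params$spacing_mm / 2)
  }
  if (is.null(anat)) anat <- .phantom_anatomy(grid, params)
  if (!use_current_rng) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  spacing_c <- max(params$ctrl_spacing_mm, 4 * max(grid$spacing))
  lattice <- bspline_lattice(grid, spacing_c)
  analytic <- function(pts) {
    u <- matrix(0, nrow(pts), 3)
    if (params$bladder_scale != 1)
      u <- u + .radial_component(pts, anat$bladder_center, anat$bladder_semi,
                                 params$bladder_scale, 35 * anat$scale)
    if (params$rectum_scale != 1)
      u <- u + .radial_tube_component(pts, anat$rectum_center[1:2],
                                      anat$rectum_radius, anat$rectum_zlim,
                                      params$rectum_scale, 25 * anat$scale)
    if (params$target_shift_mm != 0) {
      dir <- params$target_shift_dir
      dir <- dir / sqrt(sum(dir^2))
      u <- u + .shift_component(pts, anat$ctv_center,
                                params$target_shift_mm * dir,
                                40 * anat$scale, 90 * anat$scale)
    }
    u
  }
  base <- fit_displacement_field(analytic, lattice)$control_disp
  nrand <- lattice$size
  raw <- array(rnorm(prod(nrand) * 3), c(nrand, 3))
  for (c in 1:3)
    raw[, , , c] <- array(smooth3_cpp(raw[, , , c], nrand, 1L), nrand)
  mx <- max(abs(raw))
  cap <- min(params$deform_mm, 0.39 * spacing_c)
  rand <- if (mx > 0 && params$deform_mm > 0) raw / mx * 0.8 * cap else raw * 0
  damp <- 1
  for (attempt in 1:5) {
    df <- displacement_field(lattice, base + rand * damp)
    if (params$deform_mm == 0 && params$bladder_scale == 1 &&
        params$rectum_scale == 1 && params$target_shift_mm == 0)
      return(df)
    if (jacobian_min(df, grid, stride = 2L) > 0.05) return(df)
    damp <- damp * 0.7
  }
  stop("deformation folds even after damping; reduce deform_mm or organ scales")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Degrade a planning CT into a fraction-day CBCT
#'
#' Applies the ground-truth deformation then the rigid setup transform,
#' reframes into machine coordinates (scan center at the origin), crops to a
#' cylindrical field of view, and adds radial cupping, a global HU shift and
#' Gaussian noise.  Voxels outside the FOV are exactly -1000 HU.
#'
#' @param ct planning [image_volume].
#' @param true_rigid [rigid_transform] mapping planning-CT points to CBCT
#'   (machine) points; for a perfect setup this is the pure -isocenter shift.
#' @param true_dvf ground-truth [displacement_field] (pull, fraction to
#'   planning), or `NULL` for none.
#' @param params [phantom_params] (degradation settings).
#' @param seed integer seed for the noise draw (standalone use).
#' @param isocenter planning-CT isocenter (mm); defaults to the point the
#'   rigid transform maps to the scan center.
#' @param use_current_rng draw noise from the active RNG stream.
#' @return CBCT [image_volume] with a `"fov"` attribute (logical FOV mask).
#' @export
degrade_to_cbct <- function(ct, true_rigid, true_dvf, params, seed = 1L,
                            isocenter = NULL, use_current_rng = FALSE) {
  if (!use_current_rng) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  if (is.null(isocenter))
    isocenter <- drop(apply_rigid(invert_rigid(true_rigid), matrix(0, 1, 3)))
  n <- ct$grid$size
  nz_c <- max(2L, round(params$fov_z_frac * n[3]))
  iso_idx <- physical_to_voxel(isocenter, ct$grid)
  k0 <- round(iso_idx[3] - nz_c / 2)
  k0 <- max(0L, min(n[3] - nz_c, k0))
  origin_c <- drop(.v2p(matrix(c(0, 0, k0), 1), ct$grid)) - isocenter
  cbct_grid <- image_grid(c(n[1], n[2], nz_c), ct$grid$spacing, origin_c,
                          ct$grid$direction)
  ext <- min((n - 1) * ct$grid$spacing)
  r_fov <- params$fov_radius_frac * 110 * ext / 237.5
  if (r_fov > min((n[1:2] - 1) * ct$grid$spacing[1:2]) / 2)
    stop("CBCT FOV radius exceeds the CT extent")
  tf <- list(invert_rigid(true_rigid))
  if (!is.null(true_dvf)) tf <- c(tf, list(true_dvf))
  vol <- resample(ct, cbct_grid, tf, fill = -1000)
  co <- .coord_arrays(cbct_grid)
  rho2 <- co$x^2 + co$y^2
  fov <- rho2 <= r_fov^2
  vals <- vol$values
  if (params$cupping_hu != 0 || params$hu_shift != 0)
    vals[fov] <- vals[fov] + params$hu_shift +
      params$cupping_hu * (rho2[fov] / r_fov^2 - 0.5)
  if (params$noise_sd > 0)
    vals[fov] <- vals[fov] + rnorm(sum(fov), 0, params$noise_sd)
  vals[!fov] <- -1000
  out <- image_volume(vals, cbct_grid, unit = "HU", role = "cbct")
  attr(out, "fov") <- fov
  out
}

#' Generate a synthetic phantom case with known ground truth
#'
#' Builds a pelvis-like planning CT with nine labeled structures plus
#' CTV/PTV, a 4-field box plan (45 Gy full course) with the isocenter at the
#' PTV centroid, a reference dose, and a degraded fraction-day CBCT derived
#' from the CT by a known rigid setup error and a known smooth deformation.
#' Fraction-day ground-truth structures are propagated by the same composite
#' transform, so downstream registration accuracy can be scored exactly.
#' Deterministic given `(params, seed)`.
#'
#' @param params [phantom_params].
#' @param seed integer seed; one RNG stream per case, sub-stages draw in
#'   fixed order (rigid, deformation, CBCT noise).
#' @param compute_dose calculate the reference dose (skip for tests that
#'   only exercise registration).
#' @return An object of class `phantom_case`.
#' @export
generate_case <- function(params = phantom_params(), seed = 1L,
                          compute_dose = TRUE) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- params$size
  grid <- image_grid(n, params$spacing_mm, -(n - 1) * params$spacing_mm / 2)
  anat <- .phantom_anatomy(grid, params)
  ss <- anat$structures
  hu <- .phantom_hu(grid, anat)
  ct <- image_volume(hu, grid, unit = "HU", role = "planning_ct")

  # plan: isocenter at the PTV centroid, snapped to a voxel center
  ptv_idx <- which(ss$masks$PTV, arr.ind = TRUE) - 1
  iso <- drop(.v2p(matrix(round(colMeans(ptv_idx)), 1), grid))
  beams <- lapply(c(0, 90, 180, 270), function(g) {
    th <- g * pi / 180
    u <- c(cos(th), sin(th), 0)
    ppts <- .v2p(ptv_idx, grid)
    rel <- sweep(ppts, 2L, iso, `-`)
    list(gantry_angle = g, source_axis_distance = params$sad_mm,
         aperture = list(half_x = max(abs(rel %*% u)) + params$aperture_margin_mm,
                         half_y = max(abs(rel[, 3])) + params$aperture_margin_mm),
         weight = 1)
  })
  plan <- plan_info(isocenter = iso, prescription_dose = params$prescription_gy,
                    number_of_fractions = params$n_fractions, beams = beams)

  # 1) rigid setup error (draws first)
  t_err <- runif(3, -params$rigid_mm, params$rigid_mm)
  ang <- runif(3, -params$rigid_deg, params$rigid_deg) * pi / 180
  true_rigid <- rigid_transform(ang, translation = t_err - iso, center = iso)

  # 2) ground-truth deformation
  true_dvf <- sample_deformation(params, grid = grid, anat = anat,
                                 use_current_rng = TRUE)

  # 3) CBCT degradation (noise draw last)
  cbct <- degrade_to_cbct(ct, true_rigid, true_dvf, params,
                          isocenter = iso, use_current_rng = TRUE)

  comp <- list(invert_rigid(true_rigid), true_dvf)
  fmasks <- lapply(ss$masks, function(m)
    resample_mask(m, grid, cbct$grid, comp))
  fraction_structures <- structure_set(fmasks, cbct$grid, ss$roles)

  reference_dose <- NULL
  if (compute_dose) {
    reference_dose <- compute_plan_dose(ct, plan, normalization = "ptv_d98",
                                        ptv_mask = ss$masks$PTV,
                                        mu_per_rho = params$mu_per_rho)
    plan$output_factor <- attr(reference_dose, "output_factor")
  }
  structure(list(planning_ct = ct, structures = ss, plan = plan,
                 reference_dose = reference_dose, cbct = cbct,
                 fraction_structures = fraction_structures,
                 true_rigid = true_rigid, true_dvf = true_dvf,
                 seed = as.integer(seed), params = params, anatomy = anat),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case seed %d: CT %s, CBCT %s, %d structures\n",
              x$seed, paste(x$planning_ct$grid$size, collapse = "x"),
              paste(x$cbct$grid$size, collapse = "x"),
              length(x$structures$masks)))
  invisible(x)
}

#' Write a phantom case to a fixture directory
#'
#' @param case a [phantom_case].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$planning_ct, file.path(dir, "planning_ct"))
  write_volume(case$cbct, file.path(dir, "cbct"))
  if (!is.null(case$reference_dose))
    write_volume(case$reference_dose, file.path(dir, "reference_dose"))
  write_structures(case$structures, file.path(dir, "structures.json"))
  write_structures(case$fraction_structures,
                   file.path(dir, "fraction_structures.json"))
  write_plan(case$plan, file.path(dir, "plan.json"))
  truth <- list(seed = case$seed,
                rigid = list(angles = case$true_rigid$angles,
                             translation = case$true_rigid$translation,
                             center = case$true_rigid$center),
                dvf = list(control_grid = grid_to_list(case$true_dvf$control_grid),
                           control_disp = as.numeric(case$true_dvf$control_disp)),
                cbct_fov = rle_encode(attr(case$cbct, "fov")))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom case from a fixture directory
#'
#' @param dir directory written by [write_fixture_case].
#' @return A `phantom_case` (without the internal anatomy description).
#' @export
read_fixture_case <- function(dir) {
  ct <- read_image_series(file.path(dir, "planning_ct"), role = "planning_ct")
  cbct <- read_image_series(file.path(dir, "cbct"), role = "cbct")
  dose_path <- file.path(dir, "reference_dose")
  dose <- if (file.exists(paste0(dose_path, ".json"))) read_dose(dose_path) else NULL
  ss <- read_structures(file.path(dir, "structures.json"))
  fss <- read_structures(file.path(dir, "fraction_structures.json"))
  plan <- read_plan(file.path(dir, "plan.json"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  cg <- grid_from_list(truth$dvf$control_grid)
  dvf <- displacement_field(cg, array(truth$dvf$control_disp, c(cg$size, 3)))
  rigid <- rigid_transform(truth$rigid$angles, truth$rigid$translation,
                           truth$rigid$center)
  attr(cbct, "fov") <- rle_decode(truth$cbct_fov, cbct$grid$size)
  structure(list(planning_ct = ct, structures = ss, plan = plan,
                 reference_dose = dose, cbct = cbct,
                 fraction_structures = fss,
                 true_rigid = rigid, true_dvf = dvf,
                 seed = truth$seed, params = NULL, anatomy = NULL),
            class = "phantom_case")
}
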