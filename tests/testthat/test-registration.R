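# Rigid and deformable registration.

test_that("prealignment follows the isocenter-first branch logic", {
  case <- small_case()
  tf <- prealign(case$planning_ct, case$cbct, c(10, -20, 5))
  expect_equal(tf$translation, c(-10, 20, -5))
  expect_equal(tf$angles, c(0, 0, 0))
  expect_equal(attr(tf, "branch"), "isocenter")
  # absent isocenter, both grids centered at the origin -> identity
  g <- image_grid(c(10, 10, 10), 2, rep(-9, 3))
  v <- image_volume(array(0, g$size), g, unit = "HU", role = "planning_ct")
  tf0 <- prealign(v, v, NULL)
  expect_equal(tf0$translation, c(0, 0, 0))
  expect_equal(attr(tf0, "branch"), "geometry")
  # absent isocenter, offset grids -> geometric-center alignment:
  # the fixed center must map onto the moving center (pull convention)
  g2 <- image_grid(c(10, 10, 10), 2, rep(-9, 3) + c(3, 0, 0))
  v2 <- image_volume(array(0, g$size), g2, unit = "HU", role = "cbct")
  tfg <- prealign(v2, v, NULL)
  ctr_fixed <- adaptcheck:::grid_center(g2)
  expect_equal(transform_points(tfg, matrix(ctr_fixed, 1)),
               matrix(adaptcheck:::grid_center(g), 1))
})

test_that("registering a volume to itself returns the identity init", {
  case <- identity_case()
  ct <- case$planning_ct
  init <- prealign(ct, ct, NULL)
  tf <- register_rigid(ct, ct, init,
                       registration_config(max_iterations = c(40, 20, 10)))
  expect_lt(sqrt(sum(tf$translation^2)), 0.1)
  expect_lt(adaptcheck:::rotation_angle(tf) * 180 / pi, 0.05)
})

test_that("a known translation and rotation are recovered exactly enough", {
  case <- small_case()
  ct <- case$planning_ct
  truth <- rigid_transform(c(0, 0, 2 * pi / 180), c(5, -3, 2))
  moving <- resample(ct, ct$grid, invert_rigid(truth))
  cfg <- registration_config(metric = "mean_squared_difference")
  tf <- register_rigid(ct, moving, prealign(ct, moving, NULL), cfg)
  ctr <- matrix(c(0, 0, 0), 1)
  terr <- sqrt(sum((transform_points(tf, ctr) -
                      transform_points(truth, ctr))^2))
  rel <- compose_rigid(invert_rigid(tf), truth)
  expect_lt(terr, 0.5)
  expect_lt(adaptcheck:::rotation_angle(rel) * 180 / pi, 0.2)
})

test_that("B-spline registration of identical images stays at identity", {
  case <- small_case()
  ct <- case$planning_ct
  df <- register_bspline(ct, ct, config = fast_config()$registration)
  u <- disp_at(df, adaptcheck:::grid_points(ct$grid))
  expect_lt(max(abs(u)), 0.5)
})

test_that("a known smooth warp is recovered well enough to propagate masks", {
  case <- small_case()
  ct <- case$planning_ct
  truth <- case$true_dvf
  fx <- warp_image(ct, truth)
  df <- register_bspline(fx, ct, config = fast_config()$registration)
  g <- ct$grid
  # masks with visible intensity boundaries; the low-contrast bladder is
  # exactly what the structure-guided ROI stage exists for
  for (nm in c("pelvis", "femoral_head_l")) {
    gt <- propagate_mask(case$structures$masks[[nm]], g, truth)
    est <- propagate_mask(case$structures$masks[[nm]], g, df)
    rigid_only <- dsc(case$structures$masks[[nm]], gt)
    expect_gte(dsc(est, gt), 0.90, label = nm)
    expect_gte(dsc(est, gt), rigid_only, label = nm)
  }
})

test_that("increasing the smoothness weight shrinks the field", {
  case <- small_case()
  ct <- case$planning_ct
  fx <- warp_image(ct, case$true_dvf)
  maxu <- vapply(c(0.05, 2, 50), function(w) {
    cfg <- registration_config(smoothness_weight = w,
                               bspline_iterations = c(15L, 8L))
    df <- register_bspline(fx, ct, config = cfg)
    max(abs(disp_at(df, adaptcheck:::grid_points(ct$grid))))
  }, numeric(1))
  expect_true(maxu[2] <= maxu[1] + 1e-6)
  expect_true(maxu[3] <= maxu[2] + 1e-6)
})

test_that("mask propagation through a constant field is an exact shift", {
  g <- image_grid(c(16, 16, 16), 2, rep(-15, 3))
  lat <- adaptcheck:::bspline_lattice(g, 8)
  df <- fit_displacement_field(function(p)
    matrix(rep(c(2, 0, 0), each = nrow(p)), ncol = 3), lat)
  m <- array(FALSE, g$size); m[6:10, 6:10, 6:10] <- TRUE
  shifted <- propagate_mask(m, g, df)
  expect_identical(shifted[5:9, 6:10, 6:10], m[6:10, 6:10, 6:10])
  expect_equal(sum(shifted), sum(m))
  # identity field leaves masks untouched
  expect_identical(propagate_mask(m, g, displacement_field(lat)), m)
})

test_that("volume change under a radial field matches the analytic Jacobian", {
  g <- image_grid(c(40, 40, 40), 2, rep(-39, 3))
  lat <- adaptcheck:::bspline_lattice(g, 10)
  scale <- 1.3
  df <- fit_displacement_field(function(p)
    adaptcheck:::.radial_component(p, c(0, 0, 0), c(15, 15, 15), scale, 20),
    lat)
  co <- adaptcheck:::.coord_arrays(g)
  ball <- co$x^2 + co$y^2 + co$z^2 <= 15^2
  grown <- propagate_mask(ball, g, df)
  expect_lt(abs(sum(grown) / sum(ball) - scale), 0.05 * scale)
})
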