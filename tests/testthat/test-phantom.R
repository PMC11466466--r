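# Synthetic phantom: determinism, ground-truth consistency, degradation.

test_that("generation is bit-reproducible for equal (params, seed)", {
  p <- small_params()
  a <- generate_case(p, seed = 9, compute_dose = FALSE)
  b <- generate_case(p, seed = 9, compute_dose = FALSE)
  expect_identical(a$planning_ct$values, b$planning_ct$values)
  expect_identical(a$cbct$values, b$cbct$values)
  expect_identical(a$true_dvf$control_disp, b$true_dvf$control_disp)
  expect_identical(a$true_rigid$translation, b$true_rigid$translation)
  expect_identical(a$fraction_structures$masks, b$fraction_structures$masks)
})

test_that("bladder volume change tracks the requested factor", {
  case <- cached("bladder13",
                 generate_case(phantom_params(bladder_scale = 1.3), seed = 3,
                               compute_dose = FALSE))
  ratio <- sum(case$fraction_structures$masks$bladder) /
    sum(case$structures$masks$bladder)
  expect_gte(ratio, 1.2)
  expect_lte(ratio, 1.4)
})

test_that("identity motion and zero degradation give a crop-only CBCT", {
  case <- identity_case()
  g <- case$planning_ct$grid
  cg <- case$cbct$grid
  k0 <- round(adaptcheck:::.p2v(matrix(cg$origin + case$plan$isocenter, 1), g))[3]
  sub <- case$planning_ct$values[, , (k0 + 1):(k0 + cg$size[3])]
  fov <- attr(case$cbct, "fov")
  expect_identical(case$cbct$values[fov], sub[fov])
  expect_true(all(case$cbct$values[!fov] == -1000))
  for (nm in names(case$structures$masks))
    expect_identical(case$fraction_structures$masks[[nm]],
                     case$structures$masks[[nm]][, , (k0 + 1):(k0 + cg$size[3])],
                     label = nm)
})

test_that("cupping bias is analytic on a uniform water phantom", {
  g <- image_grid(c(48, 48, 24), 2.5, c(-58.75, -58.75, -28.75))
  water <- image_volume(array(0, g$size), g, unit = "HU", role = "planning_ct")
  p <- phantom_params(size = c(48, 48, 24), cupping_hu = 80, hu_shift = 0,
                      noise_sd = 0)
  tf <- rigid_transform()  # identity motion, isocenter at 0
  cb <- degrade_to_cbct(water, tf, NULL, p, isocenter = c(0, 0, 0))
  fov <- attr(cb, "fov")
  co <- adaptcheck:::.coord_arrays(cb$grid)
  r2 <- (co$x^2 + co$y^2)[fov]
  # the generator's FOV radius: fraction of the nominal body radius scaled
  # to the grid extent
  ext <- min((g$size - 1) * g$spacing)
  r_fov <- p$fov_radius_frac * 110 * ext / 237.5
  vals <- cb$values[fov]
  # exact radial bias: cupping * ((r/R)^2 - 1/2)
  expect_lt(max(abs(vals - 80 * (r2 / r_fov^2 - 0.5))), 1e-9)
  edge <- vals[which.max(r2)]
  center <- vals[which.min(r2)]
  expect_equal(edge - center, 80 * (max(r2) - min(r2)) / r_fov^2,
               tolerance = 1e-6)
  expect_true(all(cb$values[!fov] == -1000))
})

test_that("ground-truth fraction structures equal composite propagation", {
  case <- small_case()
  comp <- list(invert_rigid(case$true_rigid), case$true_dvf)
  for (nm in c("CTV", "bladder", "pelvis")) {
    prop <- propagate_mask(case$structures$masks[[nm]], case$planning_ct$grid,
                           comp, case$cbct$grid)
    expect_identical(prop, case$fraction_structures$masks[[nm]], label = nm)
    expect_equal(dsc(prop, case$fraction_structures$masks[[nm]]), 1.0)
  }
})

test_that("the ground-truth deformation never folds", {
  case <- small_case()
  expect_gt(adaptcheck:::jacobian_min(case$true_dvf, case$planning_ct$grid,
                                      stride = 2L), 0.05)
})

test_that("sample_deformation honors magnitude zero and determinism", {
  p <- small_params(bladder_scale = 1, rectum_scale = 1, deform_mm = 0,
                    target_shift_mm = 0)
  df <- sample_deformation(p, seed = 4)
  expect_equal(max(abs(df$control_disp)), 0)
  p2 <- small_params()
  d1 <- sample_deformation(p2, seed = 4)
  d2 <- sample_deformation(p2, seed = 4)
  expect_identical(d1$control_disp, d2$control_disp)
  # magnitude bound: dense displacement below the control-point cap
  pts <- adaptcheck:::grid_points(d1$control_grid)
  expect_lte(max(abs(disp_at(d1, pts))),
             max(abs(d1$control_disp)) + 1e-9)
})

test_that("PTV contains CTV and targets sit inside the body", {
  case <- small_case()
  m <- case$structures$masks
  expect_true(all(m$PTV[m$CTV]))
  expect_true(all(m$skin[m$PTV]))
  expect_gt(sum(m$CTV), 200)
})

test_that("a too-small grid errors with advice", {
  expect_error(generate_case(phantom_params(size = c(24, 24, 24)), seed = 1),
               "cannot fit")
})
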