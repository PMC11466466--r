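# HU calibration (synthetic-CT stand-in) and combined-CT splicing.

test_that("calibration is the identity when CBCT equals the aligned CT", {
  case <- identity_case()
  ct_al <- resample(case$planning_ct, case$cbct$grid,
                    invert_rigid(case$true_rigid))
  sct <- calibrate_hu(case$cbct, ct_al)
  fov <- attr(case$cbct, "fov")
  expect_lt(max(abs(sct$values[fov] - case$cbct$values[fov])), 1)
})

test_that("a constant HU shift is removed", {
  case <- identity_case()
  ct_al <- resample(case$planning_ct, case$cbct$grid, invert_rigid(case$true_rigid))
  shifted <- case$cbct
  fov <- attr(case$cbct, "fov")
  shifted$values[fov] <- shifted$values[fov] + 30
  sct <- calibrate_hu(shifted, ct_al)
  # uniform interior regions: compare against the aligned CT away from edges
  gr <- adaptcheck:::.image_gradient(ct_al$values, ct_al$grid)
  flat <- fov & sqrt(gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2) < 5
  expect_lt(max(abs(sct$values[flat] - ct_al$values[flat])), 5)
})

test_that("the calibration mapping is monotone non-decreasing", {
  case <- small_case()
  ct_al <- resample(case$planning_ct, case$cbct$grid, invert_rigid(case$true_rigid))
  sct <- calibrate_hu(case$cbct, ct_al)
  m <- attr(sct, "mapping")
  expect_true(all(diff(m$output) >= 0))
})

test_that("too few voxel pairs is an error", {
  g <- image_grid(c(5, 5, 5), 2, rep(0, 3))
  v <- image_volume(array(0, g$size), g, unit = "HU", role = "cbct")
  expect_error(calibrate_hu(v, v), "1000")
})

test_that("the combined CT partitions into exterior, blend, interior", {
  case <- small_case()
  rigid <- case$true_rigid
  ct_al <- resample(case$planning_ct, case$cbct$grid, rigid)
  sct <- calibrate_hu(case$cbct, ct_al)
  comb <- build_combined_ct(case$planning_ct, sct, rigid)
  fov <- attr(comb, "fov")
  interior <- attr(comb, "interior")
  w <- attr(comb, "blend")
  exterior <- !fov
  blendzone <- fov & !interior
  # exact partition
  expect_true(all(exterior | blendzone | interior))
  expect_equal(sum(exterior) + sum(blendzone) + sum(interior),
               prod(case$planning_ct$grid$size))
  # outside-FOV voxels are bit-equal to the planning CT
  expect_identical(comb$values[exterior], case$planning_ct$values[exterior])
  # interior voxels are bit-equal to the resampled calibrated sCT
  s_res <- resample(sct, case$planning_ct$grid, rigid, fill = -1000)
  expect_identical(comb$values[interior], s_res$values[interior])
  expect_true(all(w[interior] == 1) && all(w[exterior] == 0))
})

test_that("an undegraded, unmoved phantom returns the planning CT", {
  case <- identity_case()
  rigid <- case$true_rigid      # pure isocenter shift, grid-aligned
  ct_al <- resample(case$planning_ct, case$cbct$grid, invert_rigid(rigid))
  sct <- calibrate_hu(case$cbct, ct_al)
  comb <- build_combined_ct(case$planning_ct, sct, rigid)
  expect_lt(max(abs(comb$values - case$planning_ct$values)), 2)
})

test_that("deformed-CT production preserves the HU range", {
  case <- small_case()
  g <- case$planning_ct$grid
  dpct <- make_deformed_ct(case$planning_ct, case$true_dvf)
  expect_equal(dpct$role, "dpct")
  expect_gte(min(dpct$values), min(case$planning_ct$values))
  expect_lte(max(dpct$values), max(case$planning_ct$values))
  # identity field: dpCT equals the planning CT
  lat <- adaptcheck:::bspline_lattice(g, 20)
  dp0 <- make_deformed_ct(case$planning_ct, displacement_field(lat))
  expect_equal(dp0$values, case$planning_ct$values, tolerance = 1e-12)
})
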