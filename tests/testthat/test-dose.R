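# Ray-tracing dose engine.

water_ct <- function(n = c(61, 61, 61), spacing = 4) {
  g <- image_grid(n, spacing, -(n - 1) * spacing / 2)
  image_volume(array(0, n), g, unit = "HU", role = "planning_ct")
}

single_beam_plan <- function(gantry = 0, half = 50)
  plan_info(isocenter = c(0, 0, 0), prescription_dose = 45,
            beams = list(list(gantry_angle = gantry,
                              source_axis_distance = 1000,
                              aperture = list(half_x = half, half_y = half),
                              weight = 1)))

test_that("the HU-to-density table hits its knots and interpolates", {
  g <- image_grid(c(5, 1, 1), 1, c(0, 0, 0))
  ct <- image_volume(array(c(-1000, 0, 500, 1000, 3000), c(5, 1, 1)), g,
                     unit = "HU", role = "planning_ct")
  d <- hu_to_density(ct)
  expect_equal(as.numeric(d$values), c(0, 1, 1.3, 1.6, 2.9))
  dd <- dose_volume(array(1, c(5, 1, 1)), g, 45)
  expect_error(hu_to_density(dd), "HU")
})

test_that("radiological depth integrates exactly through water and slabs", {
  ct <- water_ct()
  dens <- hu_to_density(ct)
  expect_equal(radiological_depth(dens, c(0, -120, 0), c(0, -20, 0)), 10)
  expect_equal(radiological_depth(dens, c(0, -500, 300), c(0, -400, 300)), 0)
  # oblique ray through a two-density slab: analytic segment sum
  n <- c(40, 40, 40); sp <- 2.5
  g <- image_grid(n, sp, -(n - 1) * sp / 2)
  hu <- array(0, n)
  co <- adaptcheck:::.coord_arrays(g)
  hu[co$x >= 0] <- 1000   # density 1.6 on the +x side, boundary at x = 0
  dens2 <- hu_to_density(image_volume(hu, g, unit = "HU", role = "planning_ct"))
  src <- c(-40, -37, 3.1); tgt <- c(40, 33, -11.7)
  L <- sqrt(sum((tgt - src)^2))
  tstar <- (0 - src[1]) / (tgt[1] - src[1])
  analytic <- L * (1.0 * tstar + 1.6 * (1 - tstar)) / 10
  got <- radiological_depth(dens2, src, tgt)
  expect_equal(got, analytic, tolerance = 1e-9)
  # reversal symmetry
  expect_equal(radiological_depth(dens2, tgt, src), got, tolerance = 1e-9)
})

test_that("on-axis dose follows attenuation times inverse square exactly", {
  ct <- water_ct()
  d <- compute_plan_dose(ct, single_beam_plan(), normalization = "isocenter")
  dens <- hu_to_density(ct)
  src <- c(0, -1000, 0)
  p1 <- c(0, -40, 0); p2 <- c(0, 40, 0)
  d1 <- d$values[31, 21, 31]; d2 <- d$values[31, 41, 31]
  dep <- radiological_depth(dens, src, p1) - radiological_depth(dens, src, p2)
  pred <- exp(-0.05 * dep) * sum((p2 - src)^2) / sum((p1 - src)^2)
  expect_equal(d1 / d2, pred, tolerance = 1e-6)
})

test_that("isocenter normalization and penumbra decay contracts hold", {
  ct <- water_ct()
  plan4 <- plan_info(isocenter = c(0, 0, 0), prescription_dose = 45,
                     beams = lapply(c(0, 90, 180, 270), function(gn)
                       list(gantry_angle = gn, source_axis_distance = 1000,
                            aperture = list(half_x = 50, half_y = 50),
                            weight = 1)))
  d <- compute_plan_dose(ct, plan4, normalization = "isocenter")
  pts <- adaptcheck:::grid_points(ct$grid)
  sph <- array(rowSums(pts^2) <= 100, ct$grid$size)
  expect_equal(mean(d$values[sph]), 45, tolerance = 1e-3)
  # laterally far outside every aperture
  expect_lt(d$values[1, 31, 1], 1e-3 * 45)
})

test_that("dose is invariant to a global beam-weight scale", {
  ct <- water_ct(c(41, 41, 41))
  p1 <- single_beam_plan()
  p2 <- single_beam_plan()
  p2$beams[[1]]$weight <- 2
  d1 <- compute_plan_dose(ct, p1, normalization = "isocenter")
  d2 <- compute_plan_dose(ct, p2, normalization = "isocenter")
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("on-axis dose decreases monotonically beyond the isocenter", {
  ct <- water_ct()
  d <- compute_plan_dose(ct, single_beam_plan(), normalization = "isocenter")
  axis_prof <- d$values[31, , 31]  # along y (beam direction), y index grows
  beyond <- axis_prof[32:55]
  expect_true(all(diff(beyond) < 0))
})

test_that("invalid plans are rejected", {
  ct <- water_ct(c(21, 21, 21))
  expect_error(compute_plan_dose(ct, plan_info(isocenter = c(0, 0, 0))),
               "no beams")
  p <- single_beam_plan()
  p$isocenter <- c(5000, 0, 0)
  expect_error(compute_plan_dose(ct, p), "outside")
  expect_error(compute_plan_dose(ct, single_beam_plan(),
                                 normalization = "plan"), "output_factor")
})
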