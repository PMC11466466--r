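# Geometry core: grids, transforms, displacement fields, resampling.

test_that("voxel/physical conversion matches the affine definition", {
  g <- image_grid(c(4, 5, 6), c(2, 2, 3), c(-100, -100, -50))
  expect_equal(voxel_to_physical(c(0, 0, 0), g), c(-100, -100, -50))
  g2 <- image_grid(c(4, 4, 4), c(2, 2, 3), c(0, 0, 0))
  expect_equal(voxel_to_physical(c(1, 0, 0), g2), c(2, 0, 0))
  # x/y swap permutation direction: brute-force matrix multiply oracle
  D <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  gp <- image_grid(c(5, 5, 5), c(1, 1, 1), c(0, 0, 0), D)
  idx <- c(2, 3, 1)
  expect_equal(voxel_to_physical(idx, gp),
               as.numeric(D %*% (idx * gp$spacing)))
  expect_equal(voxel_to_physical(idx, gp), c(3, 2, 1))
})

test_that("out-of-bounds voxel indices error naming the axis", {
  g <- image_grid(c(4, 5, 6), 1, c(0, 0, 0))
  expect_error(voxel_to_physical(c(4, 0, 0), g), "axis x")
  expect_error(voxel_to_physical(c(0, 0, 9), g), "axis z")
})

test_that("physical_to_voxel round-trips exactly for in-bounds indices", {
  set.seed(3)
  g <- image_grid(c(7, 6, 5), c(1.5, 2, 2.5), c(-12, 4, 7),
                  rotation_matrix <- adaptcheck:::rotation_matrix(c(0.2, -0.1, 0.4)))
  idx <- as.matrix(expand.grid(0:6, 0:5, 0:4))
  p <- voxel_to_physical(idx, g)
  expect_equal(physical_to_voxel(p, g), idx, ignore_attr = TRUE)
})

test_that("grid validation enforces the invariants", {
  expect_error(image_grid(c(0, 2, 2), 1, c(0, 0, 0)), ">= 1")
  expect_error(image_grid(c(2, 2, 2), c(-1, 1, 1), c(0, 0, 0)), "positive")
  expect_error(image_grid(c(2, 2, 2), 1, c(0, 0, 0),
                          matrix(c(1, 0.1, 0, 0, 1, 0, 0, 0, 1), 3, 3)),
               "orthonormal")
})

test_that("rigid transforms compose and invert to identity", {
  tf <- rigid_transform(c(0.3, -0.2, 0.15), c(5, -3, 2), c(10, 0, -5))
  p <- matrix(rnorm(60), 20, 3)
  q <- transform_points(tf, p)
  back <- transform_points(invert_rigid(tf), q)
  expect_lt(max(abs(back - p)), 1e-9)
  comp <- compose_rigid(invert_rigid(tf), tf)
  expect_lt(max(abs(transform_points(comp, p) - p)), 1e-9)
  expect_error(rigid_transform(c(4, 0, 0)), "-pi")
})

test_that("resample with identity is bit-identical and shifts are exact", {
  set.seed(7)
  g <- image_grid(c(6, 5, 4), c(2, 2, 3), c(-4, -4, -4))
  v <- image_volume(array(runif(120), g$size), g, unit = "dimensionless",
                    role = "dose")
  expect_identical(resample(v)$values, v$values)
  # pure one-voxel translation along x: integer-shift oracle
  r <- resample(v, transform = rigid_transform(translation = c(2, 0, 0)),
                fill = 0)
  expect_lt(max(abs(r$values[1:5, , ] - v$values[2:6, , ])), 1e-12)
  expect_true(all(r$values[6, , ] == 0))
  # all points map outside -> uniform fill
  far <- resample(v, transform = rigid_transform(translation = c(1000, 0, 0)),
                  fill = -1)
  expect_true(all(far$values == -1))
})

test_that("resample round trip through a rigid transform is accurate", {
  g <- image_grid(c(24, 24, 24), 2, rep(-23, 3))
  smooth <- smooth_noise(c(24, 24, 24), sd = 50, hw = 2L, seed = 1)
  v <- image_volume(smooth, g, unit = "dimensionless", role = "dose")
  tf <- rigid_transform(c(0.05, 0, 0.08), c(3, -2, 1.5), c(0, 0, 0))
  fwd <- resample(v, transform = tf, fill = 0)
  back <- resample(fwd, transform = invert_rigid(tf), fill = 0)
  interior <- array(FALSE, g$size)
  interior[6:19, 6:19, 6:19] <- TRUE
  # two linear interpolations each err at most (h^2/8)|f''| ~ |second diff|/8
  d2 <- abs(smooth[1:22, , ] - 2 * smooth[2:23, , ] + smooth[3:24, , ])
  expect_lt(max(abs(back$values[interior] - v$values[interior])),
            2 * 3 * max(d2) / 8)
})

test_that("non-finite transform parameters are rejected", {
  g <- image_grid(c(4, 4, 4), 1, c(0, 0, 0))
  v <- image_volume(array(0, g$size), g, unit = "dimensionless", role = "dose")
  tf <- rigid_transform()
  tf$translation <- c(NaN, 0, 0)
  expect_error(resample(v, transform = tf), "non-finite")
})

test_that("zero-coefficient displacement fields are the identity", {
  g <- image_grid(c(10, 10, 10), 4, rep(-18, 3))
  lat <- adaptcheck:::bspline_lattice(g, 12)
  df <- displacement_field(lat)
  pts <- adaptcheck:::grid_points(g)
  expect_lt(max(abs(disp_at(df, pts))), 1e-12)
  v <- image_volume(array(runif(1000), g$size), g, unit = "dimensionless",
                    role = "dose")
  expect_equal(resample(v, transform = df)$values, v$values, tolerance = 1e-12)
})

test_that("fitted displacement fields interpolate their node samples", {
  g <- image_grid(c(12, 12, 12), 4, rep(-22, 3))
  lat <- adaptcheck:::bspline_lattice(g, 10)
  f <- function(p) cbind(2 * sin(p[, 1] / 30), cos(p[, 2] / 25) - 1,
                         0.05 * p[, 3])
  df <- fit_displacement_field(f, lat)
  nodes <- adaptcheck:::grid_points(lat)
  # interior nodes (mirror end condition distorts the outermost ring)
  int <- rowSums(adaptcheck:::.p2v(nodes, lat) < 1 |
                   adaptcheck:::.p2v(nodes, lat) > matrix(lat$size - 2,
                                                          nrow(nodes), 3,
                                                          byrow = TRUE)) == 0
  expect_lt(max(abs(disp_at(df, nodes[int, ]) - f(nodes[int, ]))), 1e-8)
})
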