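# Structure-guided ROI registration and the fixed label mapping.

test_that("the label mapping resolves overlaps to the higher label", {
  g <- image_grid(c(8, 8, 8), 2, rep(0, 3))
  skin <- array(TRUE, g$size)
  bladder <- array(FALSE, g$size); bladder[2:4, 2:4, 2:4] <- TRUE
  rectum <- array(FALSE, g$size); rectum[3:6, 3:6, 3:6] <- TRUE
  ss <- structure_set(list(skin = skin, bladder = bladder, rectum = rectum), g)
  lv <- build_label_mask(ss)
  expect_equal(lv$labels[3, 3, 3], 8L)   # bladder wins over rectum
  expect_equal(lv$labels[6, 6, 6], 6L)   # rectum only
  expect_equal(lv$labels[8, 8, 8], 1L)   # skin only
  expect_equal(unname(lv$mapping[["bladder"]]), 8L)
  expect_equal(names(roi_label_order()),
               c("air", "skin", "femoral_head_l", "femoral_head_r", "pelvis",
                 "spinal_cord", "rectum", "small_intestine", "bladder"))
  expect_error(build_label_mask(structure_set(list(bladder = bladder), g)),
               "skin")
})

test_that("voxels outside every structure are air (0)", {
  case <- small_case()
  lv <- build_label_mask(case$structures)
  outside <- !case$structures$masks$skin
  expect_true(all(lv$labels[outside] == 0L))
  expect_true(all(lv$labels >= 0L & lv$labels <= 8L))
})

test_that("label volumes serialize losslessly (every label count kept)", {
  case <- small_case()
  lv <- build_label_mask(case$structures)
  path <- file.path(tempdir(), "labels.json")
  write_label_volume(lv, path)
  lv2 <- read_label_volume(path)
  expect_identical(lv2$labels, lv$labels)
  expect_equal(table(lv2$labels), table(lv$labels))
})

test_that("identical label masks register to the identity", {
  case <- small_case()
  lv <- build_label_mask(case$structures)
  df <- register_roi(lv, lv, fast_config()$registration)
  u <- disp_at(df, adaptcheck:::grid_points(lv$grid))
  expect_lt(max(abs(u)), 0.5)
})

test_that("ROI registration is deterministic given the label masks", {
  case <- small_case()
  lv_ct <- build_label_mask(case$structures)
  # fraction-side labels from the ground-truth fraction masks, on the CT grid
  comp <- list(invert_rigid(case$true_rigid), case$true_dvf)
  fm <- lapply(case$structures$masks, function(m)
    propagate_mask(m, case$planning_ct$grid, comp, case$planning_ct$grid))
  lv_fr <- build_label_mask(structure_set(fm, case$planning_ct$grid,
                                          case$structures$roles))
  d1 <- register_roi(lv_ct, lv_fr, fast_config()$registration)
  d2 <- register_roi(lv_ct, lv_fr, fast_config()$registration)
  expect_identical(d1$control_disp, d2$control_disp)
})

test_that("a dilated bladder is recovered by mask-guided registration", {
  case <- small_case()
  g <- case$planning_ct$grid
  masks <- case$structures$masks
  dil <- masks
  dil$bladder <- adaptcheck:::mask_dilate(masks$bladder, g, 6)
  lv_ct <- build_label_mask(case$structures)
  lv_fr <- build_label_mask(structure_set(dil, g, case$structures$roles))
  df <- register_roi(lv_ct, lv_fr)
  prop <- propagate_mask(masks$bladder, g, df)
  expect_gte(dsc(prop, dil$bladder), 0.92)
})

test_that("too few shared labels is an error", {
  g <- image_grid(c(8, 8, 8), 2, rep(0, 3))
  skin <- array(TRUE, g$size)
  bl <- array(FALSE, g$size); bl[3:5, 3:5, 3:5] <- TRUE
  a <- build_label_mask(structure_set(list(skin = skin, bladder = bl), g))
  expect_error(suppressMessages(register_roi(a, a)), "fewer than 3")
})

test_that("target propagation preserves containment and flags emptiness", {
  case <- small_case()
  g <- case$planning_ct$grid
  targets <- structure_set(case$structures$masks[c("CTV", "PTV")], g)
  lat <- adaptcheck:::bspline_lattice(g, 20)
  idf <- displacement_field(lat)
  out <- propagate_targets(targets, idf)
  expect_identical(out$masks$CTV, targets$masks$CTV)
  expect_identical(out$masks$PTV, targets$masks$PTV)
  expect_true(all(out$masks$PTV[out$masks$CTV]))
  empty <- structure_set(list(CTV = array(FALSE, g$size)), g,
                         roles = c(CTV = "target"))
  expect_error(propagate_targets(empty, idf), "empty before")
})
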