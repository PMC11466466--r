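# DSC, DVH metrics, gamma analysis, fraction report, recommendation.

test_that("DSC matches voxel counting, including edge conventions", {
  m1 <- array(FALSE, c(6, 6, 6)); m1[2:3, 2:3, 2:3] <- TRUE
  expect_equal(dsc(m1, m1), 1.0)
  m2 <- array(FALSE, c(6, 6, 6)); m2[5:6, 5:6, 5:6] <- TRUE
  expect_equal(dsc(m1, m2), 0.0)
  shifted <- array(FALSE, c(6, 6, 6)); shifted[3:4, 2:3, 2:3] <- TRUE
  expect_equal(dsc(m1, shifted), 0.5)  # 2*4 / (8+8)
  expect_warning(both <- dsc(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
                 "both masks empty")
  expect_equal(both, 1.0)
  expect_error(dsc(m1, array(FALSE, c(5, 5, 5))), "same grid")
})

test_that("cumulative DVH reproduces step-function cases", {
  d <- uniform_dose(45)
  m <- array(TRUE, c(10, 10, 10))
  dvh <- cumulative_dvh(d, m, structure = "CTV")
  expect_equal(volume_at_dose(dvh, 45), 100)
  expect_equal(volume_at_dose(dvh, 45.02), 0)
  expect_equal(dose_at_volume(dvh, 99), 45, tolerance = 0.011)
  expect_equal(volume_at_dose(dvh, 100, TRUE), 100)
  # half 40 / half 50
  g <- image_grid(c(10, 10, 10), 2, rep(0, 3))
  vals <- array(40, c(10, 10, 10)); vals[6:10, , ] <- 50
  d2 <- dose_volume(vals, g, prescription = 45)
  dvh2 <- cumulative_dvh(d2, m)
  expect_equal(volume_at_dose(dvh2, 40), 100)
  expect_equal(volume_at_dose(dvh2, 45), 50)
  expect_equal(dose_at_volume(dvh2, 95), 40, tolerance = 0.011)
  expect_equal(dose_at_volume(dvh2, 50), 50, tolerance = 0.011)
  expect_true(all(diff(dvh2$cumulative_volume) <= 0))
  expect_error(cumulative_dvh(d, array(FALSE, c(10, 10, 10)),
                              structure = "CTV"), "CTV")
})

test_that("D_i and V_d agree with the voxel-sorting oracle", {
  set.seed(11)
  for (rep in 1:15) {
    n <- c(14, 14, 14)
    g <- image_grid(n, 2, rep(0, 3))
    vals <- array(runif(prod(n), 0, 50), n)
    mask <- array(runif(prod(n)) < 0.6, n)
    if (!any(mask)) next
    d <- dose_volume(vals, g, prescription = 45)
    dvh <- cumulative_dvh(d, mask)
    dv <- vals[mask]
    for (i in c(20, 50, 95, 99))
      expect_lt(abs(dose_at_volume(dvh, i) - d_at_volume_oracle(dv, i)), 0.011)
    for (dd in c(5, 20, 40))
      expect_lt(abs(volume_at_dose(dvh, dd) - v_at_dose_oracle(dv, dd)), 0.1)
  }
})

test_that("gamma handles the identity and gradient-free offset cases", {
  n <- c(12, 12, 12)
  g <- image_grid(n, 2.5, rep(0, 3))
  base <- array(1, n)
  ref <- dose_volume(base, g)
  expect_equal(as.numeric(gamma_pass_rate(ref, ref)), 100)
  ev <- dose_volume(base * 1.03, g)
  expect_equal(as.numeric(gamma_pass_rate(ref, ev)), 0)
  # scale invariance
  ref2 <- dose_volume(base * 7, g); ev2 <- dose_volume(base * 7 * 1.03, g)
  expect_equal(as.numeric(gamma_pass_rate(ref2, ev2)), 0)
  expect_error(gamma_pass_rate(dose_volume(array(0, n), g), ref), "empty")
  expect_error(gamma_criteria(dose_tolerance = 0), "positive")
})

test_that("loosening gamma criteria never lowers the pass rate", {
  set.seed(5)
  n <- c(14, 14, 14)
  g <- image_grid(n, 2.5, rep(0, 3))
  base <- 10 + smooth_noise(n, sd = 30, hw = 2L)^2
  ref <- dose_volume(base, g)
  ev <- dose_volume(base * (1 + smooth_noise(n, sd = 0.15, hw = 1L)), g)
  r22 <- as.numeric(gamma_pass_rate(ref, ev, gamma_criteria(2, 2, 10)))
  r33 <- as.numeric(gamma_pass_rate(ref, ev, gamma_criteria(3, 3, 10)))
  expect_gte(r33, r22)
})

test_that("target flags switch exactly at the clinical thresholds", {
  r_pass <- boundary_report(0.99)   # CTV V100% = 99.0 exactly
  m <- r_pass$metrics
  expect_equal(m$fraction[m$structure == "CTV" & m$metric == "V100%"], 99)
  expect_equal(m$flag[m$structure == "CTV" & m$metric == "V100%"], "pass")
  r_fail <- boundary_report(0.989)  # 98.9 fails
  mf <- r_fail$metrics
  expect_equal(mf$flag[mf$structure == "CTV" & mf$metric == "V100%"], "fail")
  # PTV V100% = 95 passes, below fails
  r95 <- boundary_report(0.95)
  m95 <- r95$metrics
  expect_equal(m95$flag[m95$structure == "PTV" & m95$metric == "V100%"], "pass")
  r949 <- boundary_report(0.949)
  m949 <- r949$metrics
  expect_equal(m949$flag[m949$structure == "PTV" & m949$metric == "V100%"], "fail")
  # D boundaries: uniform exactly 45 passes, 44.99 fails
  r45 <- boundary_report(1, hot = 45)
  m45 <- r45$metrics
  expect_true(all(m45$flag[grepl("^D", m45$metric)] == "pass"))
  r449 <- boundary_report(1, hot = 44.99)
  m449 <- r449$metrics
  expect_true(all(m449$flag[grepl("^D", m449$metric)] == "fail"))
})

test_that("identical fraction and original give zero deltas and pass", {
  r <- boundary_report(1, hot = 46)
  expect_true(all(abs(r$metrics$delta[!is.na(r$metrics$delta)]) < 1e-9))
  expect_true(r$target_pass)
  expect_equal(art_recommendation(r), "no_adaptation")
})

test_that("the recommendation policy is adapt > review > no_adaptation", {
  r_adapt <- boundary_report(0.96)
  expect_equal(art_recommendation(r_adapt), "adapt")
  # targets fine but an OAR V-metric rises by more than the margin
  r <- boundary_report(1, hot = 46)
  extra <- r$metrics[1, ]
  extra$structure <- "rectum"; extra$metric <- "V40Gy"
  extra$original <- 20; extra$fraction <- 26; extra$delta <- 6
  extra$flag <- "ok"
  r$metrics <- rbind(r$metrics, extra)
  expect_equal(art_recommendation(r), "review")
  expect_equal(art_recommendation(r, art_policy(oar_delta = 10)),
               "no_adaptation")
})

test_that("missing targets are fatal, missing OARs are flagged absent", {
  n <- c(6, 6, 6)
  g <- image_grid(n, 2, rep(0, 3))
  m <- array(TRUE, n)
  d <- dose_volume(array(46, n), g, prescription = 45)
  plan <- plan_info(isocenter = c(0, 0, 0))
  ss_no_ctv <- structure_set(list(PTV = m), g)
  expect_error(evaluate_fraction(d, ss_no_ctv, d, ss_no_ctv, plan),
               "missing target structure 'CTV'")
  ss <- structure_set(list(CTV = m, PTV = m), g)
  r <- evaluate_fraction(d, ss, d, ss, plan)
  expect_true(all(r$metrics$flag[r$metrics$structure == "bladder"] == "absent"))
})
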