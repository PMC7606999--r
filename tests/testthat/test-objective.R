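test_that("one-sided ROI penalties evaluate as hand computation", {
  # target voxels all strictly above the minimum objective -> no penalty
  expect_equal(roi_penalty(c(6.5, 7, 10), min_dose_gy = 6, min_weight = 100), 0)
  # one underdosed target voxel: 100 * (5 - 6)^2
  expect_equal(roi_penalty(5, min_dose_gy = 6, min_weight = 100), 100)
  # one overdosed OAR voxel with the rectum weights: 80 * 0.5^2
  expect_equal(roi_penalty(5, max_dose_gy = 4.5, max_weight = 80), 20)
  # equality sits on the switch but contributes zero
  expect_equal(roi_penalty(6, min_dose_gy = 6, min_weight = 100), 0)
  expect_equal(roi_penalty(4.5, max_dose_gy = 4.5, max_weight = 80), 0)
  # both-sided objective on one ROI
  expect_equal(roi_penalty(c(3, 8), min_dose_gy = 6, min_weight = 10,
                           max_dose_gy = 7, max_weight = 2),
               10 * 9 + 2 * 1)
  expect_error(roi_penalty(c(1, -2), min_dose_gy = 6, min_weight = 1),
               class = "hdrplan_input_error")
})

test_that("objective spec validates roles and weights", {
  ok <- data.frame(roi = c("t", "o"), role = c("target", "oar"),
                   min_dose_gy = c(6, NA), min_weight = c(100, NA),
                   max_dose_gy = c(NA, 4.5), max_weight = c(NA, 50))
  expect_s3_class(objective_spec(ok), "objective_spec")
  bad <- ok; bad$min_dose_gy[1] <- NA
  expect_error(objective_spec(bad), class = "hdrplan_input_error")
  bad <- ok; bad$max_dose_gy[2] <- NA
  expect_error(objective_spec(bad), class = "hdrplan_input_error")
  bad <- ok; bad$min_weight[1] <- -1
  expect_error(objective_spec(bad), class = "hdrplan_input_error")
})

test_that("dwell-time modulation term is anchored at the channel minimum", {
  # uniform times in each channel -> zero
  expect_equal(dtmf_term(c(2, 2, 2, 5, 5), c(1, 1, 1, 2, 2), p_sou = 7), 0)
  # hand evaluation: one channel (1,1,2), p = 10 -> 10 * (0+0+1)/3
  expect_equal(dtmf_term(c(1, 1, 2), c(1, 1, 1), 10), 10 / 3)
  # zero factor switches the term off
  expect_equal(dtmf_term(c(1, 9, 50), c(1, 1, 1), 0), 0)
  # channels are independent: sum of per-channel terms
  expect_equal(dtmf_term(c(1, 2, 4, 7), c(1, 1, 2, 2), 3),
               3 * ((0 + 1) / 2 + (0 + 9) / 2))
})

test_that("objective value composes penalties and modulation", {
  k <- fake_kernel(matrix(c(0.5, 0.25), 2, 1), channel_index = 1L)
  pts <- fake_points(matrix(0, 2, 3), list(t = 1L, o = 2L),
                     c(t = "target", o = "oar"))
  spec <- objective_spec(data.frame(
    roi = c("t", "o"), role = c("target", "oar"),
    min_dose_gy = c(6, NA), min_weight = c(100, NA),
    max_dose_gy = c(NA, 4.5), max_weight = c(NA, 80)))
  cfg <- optimizer_config(dtmf = 10)
  # t = 10: target dose 5 (underdose penalty 100), OAR dose 2.5 (ok),
  # single dwell -> modulation term 0
  expect_equal(objective_value(10, k, pts, spec, cfg), 100)
  # t = 11: target 5.5 underdosed, OAR 2.75 fine
  expect_equal(objective_value(11, k, pts, spec, cfg), 100 * (5.5 - 6)^2)
  # t = 20: target satisfied, OAR 5 overdosed
  expect_equal(objective_value(20, k, pts, spec, cfg), 80 * (5 - 4.5)^2)
  # feasible and uniform: zero everywhere
  expect_equal(objective_value(13, k, pts, spec, cfg), 0)
  # doubling every weight doubles F
  inst <- random_instance()
  spec2 <- inst$spec
  spec2$min_weight <- spec2$min_weight * 2
  spec2$max_weight <- spec2$max_weight * 2
  cfg1 <- optimizer_config(dtmf = 10); cfg2 <- optimizer_config(dtmf = 20)
  f1 <- objective_value(inst$times, inst$kernel, inst$points, inst$spec, cfg1)
  f2 <- objective_value(inst$times, inst$kernel, inst$points, spec2, cfg2)
  expect_equal(f2, 2 * f1)
  expect_gte(f1, 0)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(101)
  checked <- 0
  while (checked < 25) {
    inst <- random_instance()
    if (!away_from_switches(inst)) next
    cfg <- optimizer_config(dtmf = stats::runif(1, 0, 20))
    g_an <- objective_gradient(inst$times, inst$kernel, inst$points, inst$spec, cfg)
    g_fd <- fd_gradient(function(t)
      objective_value(t, inst$kernel, inst$points, inst$spec, cfg), inst$times)
    expect_lt(max(abs(g_an - g_fd) / pmax(abs(g_fd), 1)), 1e-4)
    checked <- checked + 1
  }
})

test_that("gradient has the hand-derived form on a single dwell", {
  # one underdosed target voxel, one dwell: dF/dt = 2 p (D - D0) d < 0
  d <- 0.5
  k <- fake_kernel(matrix(d, 1, 1), 1L)
  pts <- fake_points(matrix(0, 1, 3), list(t = 1L), c(t = "target"))
  spec <- objective_spec(data.frame(roi = "t", role = "target",
                                    min_dose_gy = 6, min_weight = 100,
                                    max_dose_gy = NA, max_weight = NA))
  g <- objective_gradient(2, k, pts, spec, optimizer_config(dtmf = 0))
  expect_equal(g, 2 * 100 * (2 * d - 6) * d)
  expect_lt(g, 0)
  # strictly feasible point -> zero gradient
  expect_equal(objective_gradient(14, k, pts, spec, optimizer_config(dtmf = 0)), 0)
})

test_that("modulation gradient couples through the channel minimum", {
  # channel times (1, 1, 2): argmin frozen at first index; FD on a case with
  # a unique minimum verifies the coupling on the argmin coordinate
  times <- c(1, 1.5, 2)
  cfg <- optimizer_config(dtmf = 10)
  k <- fake_kernel(matrix(1e-9, 1, 3), rep(1L, 3))  # negligible dose part
  pts <- fake_points(matrix(0, 1, 3), list(t = 1L), c(t = "target"))
  spec <- objective_spec(data.frame(roi = "t", role = "target",
                                    min_dose_gy = 1e-6, min_weight = 0,
                                    max_dose_gy = NA, max_weight = NA))
  g <- objective_gradient(times, k, pts, spec, cfg)
  # by hand: dev = (0, .5, 1); non-min: 2*10/3*dev; min: -2*10/3*sum(dev)
  expect_equal(g, c(-(20 / 3) * 1.5, (20 / 3) * 0.5, (20 / 3) * 1),
               tolerance = 1e-9)
})
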