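test_that("D_x% follows the descending-sort definition", {
  # uniform dose: every D metric equals it
  u <- dvh_curve("u", rep(6, 50), 0.001)
  expect_equal(d_percent(u, 100), 6)
  expect_equal(d_percent(u, 90), 6)
  # 10 equal-volume points, doses 1..10: D30% = 8
  c10 <- dvh_curve("c", 1:10, 0.5)
  expect_equal(d_percent(c10, 30), 8)
  # x = 100 is the minimum dose
  expect_equal(d_percent(c10, 100), 1)
  expect_error(d_percent(c10, 0), class = "hdrplan_input_error")
})

test_that("V_y% is anchored at the prescription dose", {
  u <- dvh_curve("u", rep(6, 20), 0.01, prescription = 6)
  expect_equal(v_percent(u, 150), 0)      # nothing reaches 9 Gy
  expect_equal(v_percent(u, 100), 100)    # >= comparison at the threshold
  hot <- dvh_curve("h", rep(9, 20), 0.01, prescription = 6)
  expect_equal(v_percent(hot, 150), 100)
  mix <- dvh_curve("m", c(rep(10, 4), rep(5, 6)), 0.1, prescription = 6)
  expect_equal(v_percent(mix, 150), 40)   # threshold 9 Gy -> 4 of 10 points
  expect_error(v_percent(dvh_curve("n", 1:3, 1), 150),
               class = "hdrplan_input_error")
})

test_that("D_zcc reads the hottest z cm^3", {
  c10 <- dvh_curve("c", 1:10, 0.5)  # 5 cm^3 total
  expect_equal(d_cc(c10, 2), 7)     # hottest 2 cm^3 = 4 points: 10,9,8,7
  expect_equal(d_cc(c10, 5), 1)     # z = total volume -> minimum
  expect_equal(d_cc(c10, 5), d_percent(c10, 100))
  u <- dvh_curve("u", rep(4, 8), 0.25)
  expect_equal(d_cc(u, 0.7), 4)
  expect_error(d_cc(c10, 5.5), class = "hdrplan_input_error")
})

test_that("DVH metrics match definition-based oracles on random instances", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(10:2000, 1)
    doses <- if (rep %% 3 == 0) sample(seq(0, 8, by = 0.5), n, replace = TRUE)
             else stats::runif(n, 0, 12)
    vol <- rep(0.001, n)
    curve <- dvh_curve("r", doses, 0.001, prescription = 6)
    for (x in c(5, 30, 50, 90, 100))
      expect_identical(d_percent(curve, x), oracle_d_percent(doses, vol, x))
    for (y in c(50, 100, 150, 200))
      expect_identical(v_percent(curve, y), oracle_v_percent(doses, vol, y, 6))
    for (z in c(0.001, 0.25, 0.5) * n * 0.001)
      expect_identical(d_cc(curve, z), oracle_d_cc(doses, vol, z))
  }
})

test_that("D_x% and V_y% are non-increasing in their arguments", {
  set.seed(9)
  doses <- stats::runif(500, 0, 10)
  curve <- dvh_curve("r", doses, 0.001, prescription = 6)
  dx <- vapply(seq(1, 100, by = 1), function(x) d_percent(curve, x), 0)
  expect_true(all(diff(dx) <= 0))
  vy <- vapply(seq(10, 250, by = 5), function(y) v_percent(curve, y), 0)
  expect_true(all(diff(vy) <= 0))
})

test_that("metrics are scale-equivariant in the dwell times", {
  set.seed(4)
  doses <- stats::runif(200, 0, 10)
  c1 <- dvh_curve("r", doses, 0.001, prescription = 6)
  fac <- 1.7
  c2 <- dvh_curve("r", fac * doses, 0.001, prescription = 6)
  for (x in c(10, 50, 90)) expect_equal(d_percent(c2, x), fac * d_percent(c1, x))
  expect_equal(d_cc(c2, 0.05), fac * d_cc(c1, 0.05))
  # V transforms consistently with the rescaled threshold
  expect_equal(v_percent(c2, 150), v_percent(c1, 150 / fac))
})

test_that("D90% normalization rescales exactly and is idempotent", {
  set.seed(2)
  doses <- stats::runif(300, 2, 9)
  times <- stats::runif(10, 0.5, 3)
  # factor from the ratio: current D90 = 5 -> factor 1.2 at prescription 6
  simple <- c(rep(5, 10))
  norm <- normalize_to_d90(times, simple, 0.001, 6)
  expect_equal(norm$factor, 1.2)
  # already at prescription -> unchanged
  norm1 <- normalize_to_d90(times, rep(6, 10), 0.001, 6)
  expect_equal(norm1$factor, 1)
  expect_equal(norm1$times, times)
  # linearity: after normalization the recomputed D90 equals prescription
  d90 <- d_percent(dvh_curve("t", doses, 0.001), 90)
  norm2 <- normalize_to_d90(times, doses, 0.001, 6)
  expect_equal(d_percent(dvh_curve("t", doses * norm2$factor, 0.001), 90), 6,
               tolerance = 1e-12)
  # idempotent: renormalizing gives factor 1
  norm3 <- normalize_to_d90(norm2$times, doses * norm2$factor, 0.001, 6)
  expect_lt(abs(norm3$factor - 1), 1e-9)
})

test_that("DTSD is the pooled population standard deviation", {
  expect_equal(dtsd(c(3, 3, 3)), 0)
  expect_equal(dtsd(c(1, 3)), 1)
  expect_equal(dtsd(5), 0)
  ch <- list(channel("a", rbind(c(0, 0, 0), c(0, 0, 0.25))))
  expect_equal(dtsd(plan(ch, list(c(1, 3)))), 1)
})

test_that("modulation sweep is deterministic with one row per value", {
  set.seed(19)
  inst <- random_instance()
  sw <- dtmf_sweep(inst$kernel, inst$points, inst$spec, c(0, 10, 10),
                   optimizer_config(max_iterations = 40))
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$dtsd_s[2], sw$dtsd_s[3])  # repeated value, identical result
  expect_lte(sw$dtsd_s[2], sw$dtsd_s[1])    # modulation reduces the spread
  expect_error(dtmf_sweep(inst$kernel, inst$points, inst$spec, c(5),
                          optimizer_config()),
               class = "hdrplan_input_error")
})
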