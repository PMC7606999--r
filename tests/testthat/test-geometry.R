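grid3 <- function(origin = c(0, 0, 0), spacing = 0.1, dims = c(4, 4, 4)) {
  list(origin = origin, spacing = rep(spacing, 3), dims = as.integer(dims))
}

test_that("calculation points are voxel centers", {
  g <- grid3(origin = c(1, 2, 3), spacing = 0.5, dims = c(2, 2, 2))
  occ <- array(TRUE, g$dims)
  roi <- roi_mask("t", "target", g, occ)
  pts <- sample_calc_points(list(roi), fraction = 1)
  # hand-computed centers: origin + (index - 0.5) * spacing
  ax <- function(o) o + (1:2 - 0.5) * 0.5
  expected <- as.matrix(expand.grid(x = ax(1), y = ax(2), z = ax(3)))
  expect_equal(nrow(pts$points), 8L)
  expect_equal(pts$points[order(pts$points[, 3], pts$points[, 2], pts$points[, 1]), ],
               expected[order(expected[, 3], expected[, 2], expected[, 1]), ],
               ignore_attr = TRUE)
  expect_equal(pts$voxel_volume, 0.5^3)

  # single-voxel ROI
  occ1 <- array(FALSE, g$dims); occ1[2, 1, 2] <- TRUE
  p1 <- sample_calc_points(list(roi_mask("s", "oar", g, occ1)), 1)
  expect_equal(drop(p1$points), c(1 + 1.5 * 0.5, 2 + 0.5 * 0.5, 3 + 1.5 * 0.5),
               ignore_attr = TRUE)
})

test_that("subsampling is seeded, reproducible and has round(f*n) points", {
  g <- grid3(dims = c(10, 10, 10))
  roi <- roi_mask("t", "target", g, array(TRUE, g$dims))
  a <- sample_calc_points(list(roi), 0.1, seed = 7)
  b <- sample_calc_points(list(roi), 0.1, seed = 7)
  expect_equal(nrow(a$points), 100L)
  expect_identical(a, b)
  c_ <- sample_calc_points(list(roi), 0.1, seed = 8)
  expect_false(identical(a$points, c_$points))
  # f = 1 is exhaustive and seed-independent
  expect_identical(sample_calc_points(list(roi), 1, seed = 1),
                   sample_calc_points(list(roi), 1, seed = 99))
  # per-ROI counts follow round(f * occupied)
  occ2 <- array(FALSE, g$dims); occ2[1:5, 1, 1] <- TRUE
  rois <- list(roi, roi_mask("o", "oar", g, occ2))
  p <- sample_calc_points(rois, 0.5, seed = 3)
  expect_equal(lengths(p$roi_membership), c(t = 500L, o = round(0.5 * 5)))
  # membership indices partition the point rows
  expect_equal(sort(unname(unlist(p$roi_membership))), seq_len(nrow(p$points)))
  # each sampled point represents its share of the full ROI volume
  expect_equal(unname(p$roi_point_volume * lengths(p$roi_membership)),
               c(roi_volume(rois[[1]]), roi_volume(rois[[2]])))
  expect_equal(unname(a$roi_point_volume), 0.001 * 1000 / 100)
})

test_that("mixed grids and empty ROIs are rejected", {
  g1 <- grid3(); g2 <- grid3(origin = c(0.05, 0, 0))
  r1 <- roi_mask("a", "target", g1, array(TRUE, g1$dims))
  r2 <- roi_mask("b", "oar", g2, array(TRUE, g2$dims))
  expect_error(sample_calc_points(list(r1, r2)), class = "hdrplan_input_error")
  expect_error(roi_mask("e", "oar", g1, array(FALSE, g1$dims)),
               class = "hdrplan_input_error")
  expect_error(sample_calc_points(list(r1), fraction = 0),
               class = "hdrplan_input_error")
})

test_that("roi_volume counts voxels and is additive over disjoint masks", {
  g <- grid3(dims = c(10, 10, 10))
  occ <- array(FALSE, g$dims); occ[1:10, 1:10, 1:10] <- TRUE
  expect_equal(roi_volume(roi_mask("t", "target", g, occ)), 1000 * 0.001)
  occ1 <- array(FALSE, g$dims); occ1[1:3, , ] <- TRUE
  occ2 <- array(FALSE, g$dims); occ2[4:10, , ] <- TRUE
  expect_equal(roi_volume(roi_mask("a", "oar", g, occ1)) +
                 roi_volume(roi_mask("b", "oar", g, occ2)),
               roi_volume(roi_mask("t", "target", g, occ)))
})

test_that("voxelized sphere volume approaches the analytic value", {
  spacing <- 0.05
  n <- ceiling(2.2 / spacing)
  g <- list(origin = rep(-1.1, 3), spacing = rep(spacing, 3), dims = rep(as.integer(n), 3))
  ax <- g$origin[1] + (seq_len(n) - 0.5) * spacing
  occ <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= 1
  vol <- roi_volume(roi_mask("sphere", "target", g, occ))
  expect_lt(abs(vol - 4 * pi / 3) / (4 * pi / 3), 0.02)
})

test_that("flatten/unflatten round-trips dwell times", {
  ch <- list(channel("a", rbind(c(0, 0, 0), c(0, 0, 0.25))),
             channel("b", matrix(c(1, 0, 0), 1)))
  p <- plan(ch, list(c(1, 2), 3))
  expect_equal(flatten_times(p), c(1, 2, 3))
  p2 <- unflatten_times(p, c(4, 5, 6))
  expect_equal(p2$dwell_times, list(c(4, 5), 6))
  expect_equal(flatten_times(unflatten_times(p, flatten_times(p))),
               flatten_times(p))
  expect_error(unflatten_times(p, 1:4), class = "hdrplan_input_error")
  expect_error(plan(ch, list(1, 2)), class = "hdrplan_input_error")
})

test_that("phantom JSON and plan CSV round-trip", {
  ph <- small_phantom(seed = 11, spacing = 0.25, volume = 20)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_json(ph, path)
  back <- read_phantom_json(path)
  expect_equal(length(back$channels), length(ph$channels))
  for (i in seq_along(ph$channels))
    expect_equal(back$channels[[i]]$dwell_positions, ph$channels[[i]]$dwell_positions)
  for (nm in names(ph$rois))
    expect_identical(back$rois[[nm]]$occupancy, ph$rois[[nm]]$occupancy)

  pl <- unflatten_times(plan(ph$channels),
                        seq_len(n_dwells <- sum(sapply(ph$channels, function(c) nrow(c$dwell_positions)))) * 0.37)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_plan_csv(pl, csv)
  pl2 <- read_plan_csv(csv)
  expect_equal(flatten_times(pl2), flatten_times(pl))
  expect_equal(stack_dwell_positions_test(pl2$channels),
               stack_dwell_positions_test(pl$channels))
})
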