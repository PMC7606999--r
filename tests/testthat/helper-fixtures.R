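# Shared fixtures, all built in code.

# small hand-checkable TG-43 tables; g(1) = 1 by construction
make_test_source <- function(sk = 1000, lambda = 0.01) {
  r <- c(0.1, 0.5, 1, 2, 3, 5, 10)
  source_model(
    dose_rate_constant = lambda, air_kerma_strength = sk,
    radial_dose_table = data.frame(r_cm = r,
                                   g = c(1.02, 1.01, 1.00, 0.98, 0.95, 0.90, 0.80)),
    anisotropy_table = data.frame(r_cm = r,
                                  phi_an = c(0.92, 0.95, 0.97, 0.98, 0.985, 0.99, 0.99)),
    r_min = 0.1, r_max = 10
  )
}

# pure inverse-square source: g == phi == 1, S_K * Lambda = 3600 so the
# kernel entry at distance r is exactly 1/r^2 Gy/s
unit_source <- function() {
  source_model(
    dose_rate_constant = 1, air_kerma_strength = 3600,
    radial_dose_table = data.frame(r_cm = c(0.1, 10), g = c(1, 1)),
    anisotropy_table = data.frame(r_cm = c(0.1, 10), phi_an = c(1, 1)),
    r_min = 0.1, r_max = 10
  )
}

# independent brute-force kernel: per-pair recomputation through the scalar
# point-dose function, no matrix path
oracle_kernel_values <- function(source, channels, P) {
  W <- do.call(rbind, lapply(channels, function(ch) ch$dwell_positions))
  vals <- matrix(0, nrow(P), nrow(W))
  for (i in seq_len(nrow(P)))
    for (j in seq_len(nrow(W)))
      vals[i, j] <- dose_rate_at_point(source, W[j, ], P[i, ])
  vals
}

# fabricate a calc_points object directly (for objective/gradient tests that
# do not need a voxel grid)
fake_points <- function(P, membership, roles, voxel_volume = 1e-3) {
  structure(list(points = P, voxel_volume = voxel_volume,
                 roi_membership = membership, roi_roles = roles),
            class = "calc_points")
}

# fabricate a dose kernel with given values/channel structure
fake_kernel <- function(values, channel_index) {
  structure(list(values = values, point_count = nrow(values),
                 dwell_count = ncol(values),
                 dwell_index_map = data.frame(
                   channel = channel_index,
                   position = stats::ave(channel_index, channel_index,
                                         FUN = seq_along)),
                 channel_index = channel_index),
            class = "dose_kernel")
}

# random objective/gradient test instance: <= 3 channels, <= 20 dwells,
# <= 200 points, one target + one OAR
random_instance <- function() {
  nch <- sample(1:3, 1)
  per <- sample(1:7, nch, replace = TRUE)
  k <- sum(per)
  n <- sample(20:200, 1)
  values <- matrix(stats::runif(n * k, 0.01, 0.6), n, k)
  channel_index <- rep(seq_len(nch), per)
  ntar <- sample(seq_len(n - 1), 1)
  pts <- fake_points(matrix(0, n, 3),
                     membership = list(target = seq_len(ntar),
                                       oar = seq.int(ntar + 1L, n)),
                     roles = c(target = "target", oar = "oar"))
  spec <- objective_spec(data.frame(
    roi = c("target", "oar"), role = c("target", "oar"),
    min_dose_gy = c(6, NA), min_weight = c(100, NA),
    max_dose_gy = c(NA, 4.5), max_weight = c(NA, 80)))
  times <- stats::runif(k, 0.5, 25)
  list(kernel = fake_kernel(values, channel_index), points = pts,
       spec = spec, times = times, channel_index = channel_index)
}

# TRUE when `inst` at `times` is at least `margin` away from every Heaviside
# switching surface and within-channel minimum tie
away_from_switches <- function(inst, margin = 1e-3) {
  doses <- total_dose(inst$kernel, inst$times)
  ok <- all(abs(doses[inst$points$roi_membership$target] - 6) > margin) &&
    all(abs(doses[inst$points$roi_membership$oar] - 4.5) > margin)
  for (m in unique(inst$channel_index)) {
    t <- sort(inst$times[inst$channel_index == m])
    if (length(t) > 1 && (t[2] - t[1]) < margin) ok <- FALSE
  }
  ok
}

fd_gradient <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

# coarse fast phantom for integration-style tests
small_phantom <- function(seed = 5L, spacing = 0.2, volume = 52.65) {
  make_phantom(phantom_spec("fletcher", target_volume = volume,
                            spacing = spacing, seed = seed))
}

table1_objectives <- function() make_regression_case(spacing = 0.2)$objectives

stack_dwell_positions_test <- function(channels)
  do.call(rbind, lapply(channels, function(ch) ch$dwell_positions))

# definition-based DVH oracles: direct threshold scans, no cumulative sums
oracle_d_percent <- function(doses, vol, x) {
  tot <- sum(vol)
  cand <- sort(unique(doses), decreasing = TRUE)
  for (d in cand)
    if (sum(vol[doses >= d]) / tot >= x / 100 - 1e-12) return(d)
  min(doses)
}
oracle_v_percent <- function(doses, vol, y, prescription) {
  100 * sum(vol[doses >= y / 100 * prescription]) / sum(vol)
}
oracle_d_cc <- function(doses, vol, z) {
  cand <- sort(unique(doses), decreasing = TRUE)
  for (d in cand)
    if (sum(vol[doses >= d]) >= z - 1e-12) return(d)
  min(doses)
}
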