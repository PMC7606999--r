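#' Synthetic phantom specification
#'
#' Describes a desk-scale implant-plus-anatomy phantom emulating the common
#' gynecological applicator geometries: a Fletcher tandem-and-ovoids set, a
#' double-ovoid set, a tandem-ring set, a multi-channel cylinder, and a
#' tandem-with-needles set. The target (HR-CTV) is a seeded, randomly
#' perturbed ellipsoid around the applicator; bladder, rectum and sigmoid
#' are placed anterior, posterior and superior of it.
#'
#' @param kind one of `"fletcher"`, `"double_ovoid"`, `"tandem_ring"`,
#'   `"multichannel"`, `"tandem_needles"`.
#' @param target_volume HR-CTV volume setpoint, cm^3; the voxelized mask is
#'   tuned to within 5% of it.
#' @param spacing grid spacing, cm (default 0.1, isotropic).
#' @param margin target-to-OAR surface gap, cm.
#' @param seed integer; the phantom is a pure function of this spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("fletcher", "double_ovoid", "tandem_ring",
                                  "multichannel", "tandem_needles"),
                         target_volume = 52.65, spacing = 0.1,
                         margin = 0.3, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot_number(target_volume, "target_volume", positive = TRUE)
  stopifnot_number(spacing, "spacing", positive = TRUE)
  stopifnot_number(margin, "margin", nonneg = TRUE)
  structure(list(kind = kind, target_volume = target_volume,
                 spacing = spacing, margin = margin, seed = as.integer(seed)),
            class = "phantom_spec")
}

# dwell positions along a straight segment at `step` spacing (inclusive start)
.segment_dwells <- function(start, direction, length_cm, step) {
  direction <- direction / sqrt(sum(direction^2))
  s <- seq(0, length_cm, by = step)
  t(vapply(s, function(u) start + u * direction, numeric(3)))
}

# applicator channel set + nominal target center for each kind
.applicator <- function(kind, step = 0.25) {
  tandem <- function() channel("tandem", .segment_dwells(c(0, 0, 0), c(0, 0, 1), 4.5, step), step)
  switch(kind,
    fletcher = list(center = c(0, 0, 2.0), channels = list(
      tandem(),
      channel("ovoid_left",  .segment_dwells(c(-1.4, 0, 0), c(0, 0, 1), 0.75, step), step),
      channel("ovoid_right", .segment_dwells(c(1.4, 0, 0), c(0, 0, 1), 0.75, step), step))),
    double_ovoid = list(center = c(0, 0, 0.9), channels = list(
      channel("ovoid_left",  .segment_dwells(c(-1.2, 0, 0), c(0, 0, 1), 1.0, step), step),
      channel("ovoid_right", .segment_dwells(c(1.2, 0, 0), c(0, 0, 1), 1.0, step), step))),
    tandem_ring = list(center = c(0, 0, 1.8), channels = list(
      tandem(),
      { radius <- 1.3
        n <- max(4L, floor(2 * pi * radius / step))
        ang <- 2 * pi * (seq_len(n) - 1L) / n
        channel("ring", cbind(radius * cos(ang), radius * sin(ang), 0.5), step) })),
    multichannel = list(center = c(0, 0, 1.6), channels = c(
      list(channel("central", .segment_dwells(c(0, 0, 0), c(0, 0, 1), 3.5, step), step)),
      lapply(1:6, function(i) {
        ang <- 2 * pi * (i - 1) / 6
        channel(sprintf("peripheral_%d", i),
                .segment_dwells(c(cos(ang), sin(ang), 0), c(0, 0, 1), 2.0, step), step)
      }))),
    tandem_needles = list(center = c(0, 0, 2.0), channels = c(
      list(tandem()),
      lapply(1:4, function(i) {
        ang <- pi / 4 + 2 * pi * (i - 1) / 4
        channel(sprintf("needle_%d", i),
                .segment_dwells(c(1.5 * cos(ang), 1.5 * sin(ang), 0), c(0, 0, 1), 2.5, step), step)
      })))
  )
}

# voxelize an ellipsoid on the grid: occupancy by voxel-center-inside test
.ellipsoid_mask <- function(grid, center, semi) {
  ax <- function(k) grid$origin[k] + (seq_len(grid$dims[k]) - 0.5) * grid$spacing[k]
  x2 <- ((ax(1) - center[1]) / semi[1])^2
  y2 <- ((ax(2) - center[2]) / semi[2])^2
  z2 <- ((ax(3) - center[3]) / semi[3])^2
  outer(outer(x2, y2, `+`), z2, `+`) <= 1
}

#' Generate a synthetic applicator + anatomy phantom
#'
#' Deterministically builds the channel set for the requested applicator
#' kind (dwell positions at the source step size of 0.25 cm), a perturbed
#' ellipsoidal HR-CTV tuned to the requested volume, and bladder / rectum /
#' sigmoid masks that abut the target at the configured margin without
#' overlapping it — close enough that their maximum-dose objectives are
#' active during optimization.
#'
#' @param spec a [phantom_spec()].
#' @return list with `channels` (list of [channel()]), `rois` (named list of
#'   [roi_mask()], target first), `grid`, and `spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  app <- .applicator(spec$kind)

  with_private_seed(spec$seed, {
    center <- app$center + stats::runif(3, -0.1, 0.1)
    ratios <- c(1.0, 0.9, 1.3) * stats::runif(3, 0.95, 1.05)
    s <- (spec$target_volume / (4 / 3 * pi * prod(ratios)))^(1 / 3)
    semi <- ratios * s

    m <- spec$margin
    oars <- list(
      Bladder = list(center = center + c(0, semi[2] + m + 1.6, 0.5) + stats::runif(3, -0.1, 0.1),
                     semi = c(2.2, 1.6, 2.0)),
      Rectum  = list(center = center - c(0, semi[2] + m + 1.1, 0) + stats::runif(3, -0.1, 0.1),
                     semi = c(1.1, 1.1, 2.6)),
      Sigmoid = list(center = center + c(0.3, 0.5, semi[3] + m + 1.0) + stats::runif(3, -0.1, 0.1),
                     semi = c(1.5, 1.4, 1.0))
    )

    # grid covering every structure and dwell with padding, snapped to spacing
    all_lo <- rbind(center - semi,
                    t(vapply(oars, function(o) o$center - o$semi, numeric(3))),
                    apply(stack_dwell_positions(app$channels), 2, min))
    all_hi <- rbind(center + semi,
                    t(vapply(oars, function(o) o$center + o$semi, numeric(3))),
                    apply(stack_dwell_positions(app$channels), 2, max))
    pad <- 0.4
    origin <- floor((apply(all_lo, 2, min) - pad) / spec$spacing) * spec$spacing
    upper  <- ceiling((apply(all_hi, 2, max) + pad) / spec$spacing) * spec$spacing
    grid <- list(origin = origin,
                 spacing = rep(spec$spacing, 3),
                 dims = as.integer(round((upper - origin) / spec$spacing)))

    # tune target semi-axes until the voxelized volume is within 5%
    vox <- prod(grid$spacing)
    occ_t <- NULL
    for (it in 1:25) {
      occ_t <- .ellipsoid_mask(grid, center, semi)
      v <- sum(occ_t) * vox
      if (v == 0) { semi <- semi * 1.5; next }
      if (abs(v - spec$target_volume) / spec$target_volume <= 0.05) break
      semi <- semi * (spec$target_volume / v)^(1 / 3)
      occ_t <- NULL
    }
    if (is.null(occ_t) ||
        abs(sum(occ_t) * vox - spec$target_volume) / spec$target_volume > 0.05)
      abort_config("target volume unreachable on this grid")

    rois <- list(`HR-CTV` = roi_mask("HR-CTV", "target", grid, occ_t))
    for (nm in names(oars)) {
      occ <- .ellipsoid_mask(grid, oars[[nm]]$center, oars[[nm]]$semi) & !occ_t
      rois[[nm]] <- roi_mask(nm, "oar", grid, occ)
    }

    list(channels = app$channels, rois = rois, grid = grid, spec = spec)
  })
}

#' Packaged synthetic source characterization
#'
#' Loads the synthetic Ir-192-like TG-43 table CSV shipped with the package
#' (`inst/extdata/source_ir192_synthetic.csv`). The tables are smooth
#' analytic stand-ins on the Ir-192 scale, not measured data for any real
#' source; they are labelled synthetic for that reason.
#'
#' @return a [source_model()].
#' @export
fixture_source <- function() {
  path <- system.file("extdata", "source_ir192_synthetic.csv", package = "hdrplan")
  if (!nzchar(path)) abort_config("packaged source fixture not found")
  read_source_csv(path)
}

#' Canonical regression case
#'
#' The reference test bundle: a Fletcher-style phantom at a fixed seed with
#' the standard cervix objective set (HR-CTV minimum 6.0 Gy weight 100;
#' bladder maximum 4.5 Gy weight 50; rectum and sigmoid maximum 4.5 Gy
#' weight 80), modulation factor 10, 100 iterations, dwell-time lower bound
#' 1e-6 s, initial dwell time 1 s, prescription 6 Gy.
#'
#' @param spacing grid spacing, cm; the clinical planning resolution of
#'   0.1 cm by default.
#' @return list with `phantom`, `objectives`, `config`, `prescription`,
#'   `subsample_fraction`, `source`.
#' @export
make_regression_case <- function(spacing = 0.1) {
  objectives <- objective_spec(data.frame(
    roi = c("HR-CTV", "Bladder", "Rectum", "Sigmoid"),
    role = c("target", "oar", "oar", "oar"),
    min_dose_gy = c(6.0, NA, NA, NA),
    min_weight = c(100, NA, NA, NA),
    max_dose_gy = c(NA, 4.5, 4.5, 4.5),
    max_weight = c(NA, 50, 80, 80)
  ))
  list(
    phantom = make_phantom(phantom_spec("fletcher", target_volume = 52.65,
                                        spacing = spacing, seed = 17L)),
    objectives = objectives,
    config = optimizer_config(dtmf = 10, max_iterations = 100L,
                              lower_bound = 1e-6, initial_time = 1.0),
    prescription = 6.0,
    subsample_fraction = 0.1,
    source = fixture_source()
  )
}
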