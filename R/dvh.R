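#' Cumulative dose-volume histogram data for one ROI
#'
#' Holds the per-calculation-point doses and volumes from which the DVH
#' metrics are read. Metrics use the empirical (non-interpolated) descending
#' dose sort with `>=` threshold comparisons throughout.
#'
#' @param name ROI label.
#' @param doses Gy per calculation point.
#' @param point_volume cm^3 per point (scalar voxel volume, or a vector).
#' @param prescription prescription dose, Gy (needed for V_y% metrics).
#' @return An object of class `dvh_curve`.
#' @export
dvh_curve <- function(name, doses, point_volume, prescription = NA_real_) {
  doses <- as.numeric(doses)
  if (length(doses) == 0L) abort_input("empty dose list")
  if (any(!is.finite(doses)) || any(doses < 0))
    abort_input("doses must be finite and >= 0")
  vol <- rep_len(as.numeric(point_volume), length(doses))
  if (any(vol <= 0)) abort_input("point volumes must be > 0")
  structure(list(name = as.character(name), doses = doses,
                 point_volume = vol, total_volume = sum(vol),
                 prescription = prescription),
            class = "dvh_curve")
}

# descending-sorted doses with cumulative volume; shared by the D metrics
.sorted_cumvol <- function(curve) {
  ord <- order(curve$doses, decreasing = TRUE)
  list(doses = curve$doses[ord], cumvol = cumsum(curve$point_volume[ord]))
}

#' D_x%: dose covering x% of the ROI volume
#'
#' The largest dose d such that at least x% of the total ROI volume receives
#' a dose >= d: the dose of the point at the smallest cumulative volume
#' >= x% on the descending sort. `d_percent(curve, 100)` is the ROI minimum
#' dose.
#'
#' @param curve a [dvh_curve()].
#' @param x volume percentage in (0, 100].
#' @return dose, Gy.
#' @export
d_percent <- function(curve, x) {
  stopifnot_number(x, "x", positive = TRUE)
  if (x > 100) abort_input("`x` must be <= 100")
  s <- .sorted_cumvol(curve)
  target <- x / 100 * curve$total_volume
  # guard the last entry against cumsum round-off
  i <- which(s$cumvol >= target * (1 - 1e-12))[1]
  if (is.na(i)) i <- length(s$doses)
  s$doses[i]
}

#' V_y%: fractional volume receiving y% of the prescription
#'
#' 100 x (volume with dose >= y% of the prescription dose) / total volume.
#' The threshold is anchored at the prescription, not at any plan statistic.
#'
#' @param curve a [dvh_curve()] with `prescription` set.
#' @param y dose percentage (> 0), relative to the prescription.
#' @return volume percentage in \[0, 100\].
#' @export
v_percent <- function(curve, y) {
  stopifnot_number(y, "y", positive = TRUE)
  if (is.na(curve$prescription)) abort_input("curve has no prescription dose set")
  thr <- y / 100 * curve$prescription
  100 * sum(curve$point_volume[curve$doses >= thr]) / curve$total_volume
}

#' D_zcc: dose to the hottest z cm^3
#'
#' The largest dose d such that at least z cm^3 receives >= d; the same
#' descending-sort construction as [d_percent()]. At z equal to the total
#' volume this is the ROI minimum dose.
#'
#' @param curve a [dvh_curve()].
#' @param z absolute volume, cm^3, in (0, total volume].
#' @return dose, Gy.
#' @export
d_cc <- function(curve, z) {
  stopifnot_number(z, "z", positive = TRUE)
  if (z > curve$total_volume * (1 + 1e-12))
    abort_input("`z` exceeds the ROI volume")
  s <- .sorted_cumvol(curve)
  i <- which(s$cumvol >= z * (1 - 1e-12))[1]
  if (is.na(i)) i <- length(s$doses)
  s$doses[i]
}

#' Normalize a plan so target D90% equals the prescription
#'
#' Multiplies every dwell time by `prescription / D90%(current)`. Dose is
#' linear in the dwell times, so every DVH dose metric scales by the same
#' factor and the recomputed D90% equals the prescription to round-off.
#'
#' @param times flat dwell time vector, seconds.
#' @param target_doses Gy at the target's calculation points for `times`.
#' @param point_volume cm^3 per target point.
#' @param prescription prescription dose, Gy.
#' @return list with `times` (rescaled), `factor`.
#' @export
normalize_to_d90 <- function(times, target_doses, point_volume, prescription) {
  stopifnot_number(prescription, "prescription", positive = TRUE)
  d90 <- d_percent(dvh_curve("target", target_doses, point_volume), 90)
  if (d90 <= 0) abort_degenerate("target D90% is zero; cannot normalize plan")
  factor <- prescription / d90
  list(times = times * factor, factor = factor)
}

#' Dwell time standard deviation (DTSD)
#'
#' Population standard deviation of the dwell times pooled over all channels
#' of the plan — the spread statistic tracked against the modulation factor.
#'
#' @param times flat dwell time vector, seconds (or a [plan()]).
#' @return seconds.
#' @export
dtsd <- function(times) {
  if (inherits(times, "plan")) times <- flatten_times(times)
  if (length(times) == 0L) abort_input("need >= 1 dwell time")
  sqrt(mean((times - mean(times))^2))
}

#' Sweep the dwell-time modulation factor
#'
#' Runs one full optimization per modulation-factor value on identical
#' inputs and records the resulting (un-normalized) dwell time standard
#' deviation. Increasing the factor trades dwell-time spread against the
#' dose objectives; the spread drops steeply at small factors and flattens
#' out, so very large values buy little additional smoothing.
#'
#' @param kernel,points,spec as in [optimize_dwell_times()].
#' @param dtmf_values nonnegative modulation factors (>= 2 values).
#' @param config an [optimizer_config()]; its `dtmf` is overridden per value.
#' @return data.frame with columns `dtmf`, `dtsd_s`, `objective`.
#' @export
dtmf_sweep <- function(kernel, points, spec, dtmf_values,
                       config = optimizer_config()) {
  dtmf_values <- as.numeric(dtmf_values)
  if (length(dtmf_values) < 2L || any(dtmf_values < 0))
    abort_input("`dtmf_values` must be >= 2 nonnegative values")
  rows <- lapply(dtmf_values, function(v) {
    cfg <- config; cfg$dtmf <- v
    fit <- optimize_dwell_times(kernel, points, spec, cfg)
    data.frame(dtmf = v, dtsd_s = dtsd(fit$times), objective = fit$value)
  })
  do.call(rbind, rows)
}

#' Plan quality report
#'
#' The standard evaluation metrics: target D100%, D90%, V150%; per-OAR
#' D0.1cc, D1cc, D2cc; plus the plan's DTSD.
#'
#' @param doses Gy at all calculation points.
#' @param points a [sample_calc_points()] result.
#' @param prescription prescription dose, Gy.
#' @param times flat dwell time vector (for DTSD), or NULL to omit.
#' @return data.frame with columns `roi`, `metric`, `value`, `unit`.
#' @export
plan_quality_report <- function(doses, points, prescription, times = NULL) {
  rows <- list()
  for (nm in names(points$roi_membership)) {
    idx <- points$roi_membership[[nm]]
    pv <- if (is.null(points$roi_point_volume)) points$voxel_volume
          else points$roi_point_volume[[nm]]
    curve <- dvh_curve(nm, doses[idx], pv, prescription)
    if (points$roi_roles[[nm]] == "target") {
      rows[[length(rows) + 1L]] <- data.frame(
        roi = nm,
        metric = c("D100%", "D90%", "V150%"),
        value = c(d_percent(curve, 100), d_percent(curve, 90), v_percent(curve, 150)),
        unit = c("Gy", "Gy", "%"))
    } else {
      vols <- c(0.1, 1, 2)
      vols <- vols[vols <= curve$total_volume]
      if (length(vols)) rows[[length(rows) + 1L]] <- data.frame(
        roi = nm,
        metric = sprintf("D%.3gcc", vols),
        value = vapply(vols, function(z) d_cc(curve, z), 0),
        unit = "Gy")
    }
  }
  if (!is.null(times))
    rows[[length(rows) + 1L]] <- data.frame(roi = "plan", metric = "DTSD",
                                            value = dtsd(times), unit = "s")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
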