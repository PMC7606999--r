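#' Fit an inverse HDR brachytherapy plan
#'
#' The main entry point. Runs the full inverse-planning pipeline on a
#' phantom (or any channels + ROI masks bundle): samples dose calculation
#' points from the ROI voxel grids, assembles the TG-43 dose kernel,
#' minimizes the quadratic one-sided dose objective with the dwell-time
#' modulation term under the dwell-time lower bound, and (by default)
#' normalizes the plan so that the target's D90% equals the prescription.
#'
#' @param phantom list with `channels` and `rois`, e.g. from
#'   [make_phantom()] or [read_phantom_json()].
#' @param objectives an [objective_spec()] (or a data.frame coercible to one).
#' @param source a [source_model()]; defaults to the packaged synthetic
#'   Ir-192-like characterization.
#' @param config an [optimizer_config()].
#' @param prescription prescription dose, Gy.
#' @param subsample_fraction fraction of ROI voxels used as calculation
#'   points (seeded, per ROI); 1 uses every occupied voxel.
#' @param sampling_seed seed for the voxel subsample.
#' @param normalize rescale dwell times so target D90% = prescription.
#' @param keep_kernel retain the dose kernel matrix in the returned object
#'   (costs memory, makes repeated evaluation cheap).
#' @return An object of class `hdrplan`; see Details.
#'
#' @details The returned object supports `print()`, `summary()` (DVH quality
#' report), `coef()` (optimized dwell times, seconds), `fitted()` (doses at
#' the calculation points, Gy), `predict()` (dose at new points),
#' `residuals()` (signed per-point objective violations, Gy) and `plot()`
#' (objective trace or DVH curves).
#'
#' @examples
#' ph <- make_phantom(phantom_spec("fletcher", target_volume = 40,
#'                                 spacing = 0.25, seed = 3))
#' case <- make_regression_case()
#' fit <- hdrplan(ph, case$objectives, subsample_fraction = 0.2,
#'                config = optimizer_config(max_iterations = 25))
#' fit
#' head(summary(fit)$report)
#' @export
hdrplan <- function(phantom, objectives, source = fixture_source(),
                    config = optimizer_config(), prescription = 6.0,
                    subsample_fraction = 1, sampling_seed = 1L,
                    normalize = TRUE, keep_kernel = FALSE) {
  cl <- match.call()
  if (!inherits(objectives, "objective_spec")) objectives <- objective_spec(objectives)
  if (!inherits(config, "optimizer_config"))
    abort_input("`config` must be an optimizer_config()")
  stopifnot_number(prescription, "prescription", positive = TRUE)
  if (is.null(phantom$channels) || is.null(phantom$rois))
    abort_input("`phantom` must have `channels` and `rois`")

  points <- sample_calc_points(phantom$rois, subsample_fraction, sampling_seed)
  kernel <- build_dose_kernel(source, phantom$channels, points)
  opt <- optimize_dwell_times(kernel, points, objectives, config)

  times <- opt$times
  factor <- 1
  target_name <- names(points$roi_roles)[points$roi_roles == "target"][1]
  if (is.na(target_name)) abort_input("no target ROI in the phantom")
  if (normalize) {
    tidx <- points$roi_membership[[target_name]]
    doses_raw <- total_dose(kernel, times)
    norm <- normalize_to_d90(times, doses_raw[tidx], points$voxel_volume, prescription)
    times <- norm$times
    factor <- norm$factor
  }
  doses <- total_dose(kernel, times)
  report <- plan_quality_report(doses, points, prescription, times = times)

  structure(list(
    call = cl,
    channels = phantom$channels,
    objectives = objectives,
    config = config,
    source = source,
    prescription = prescription,
    points = points,
    times = times,
    raw_times = opt$times,
    normalization_factor = factor,
    target = target_name,
    doses = doses,
    objective_value = opt$value,
    trace = opt$trace,
    n_iter = opt$n_iter,
    counts = opt$counts,
    active_bound = opt$active_bound,
    report = report,
    kernel = if (keep_kernel) kernel else NULL
  ), class = "hdrplan")
}

#' @export
print.hdrplan <- function(x, ...) {
  nd <- n_dwells(x$channels)
  cat("Inverse HDR plan fit\n")
  cat(sprintf("  %d channels, %d dwell positions; %d calculation points\n",
              length(x$channels), nd, nrow(x$points$points)))
  cat(sprintf("  objective F: %.6g after %d iterations (%d fn evals)\n",
              x$objective_value, x$n_iter, unname(x$counts["function"])))
  d90 <- x$report$value[x$report$roi == x$target & x$report$metric == "D90%"]
  cat(sprintf("  normalization factor: %.4f  (target %s D90%% = %.4g Gy)\n",
              x$normalization_factor, x$target, d90))
  cat(sprintf("  dwell times [s]: min %.4g, median %.4g, max %.4g; DTSD %.4g\n",
              min(x$times), stats::median(x$times), max(x$times), dtsd(x$times)))
  invisible(x)
}

#' @export
summary.hdrplan <- function(object, ...) {
  structure(list(report = object$report,
                 objective_value = object$objective_value,
                 n_iter = object$n_iter,
                 normalization_factor = object$normalization_factor,
                 active_bound = object$active_bound,
                 prescription = object$prescription),
            class = "summary.hdrplan")
}

#' @export
print.summary.hdrplan <- function(x, ...) {
  cat("Plan quality report (prescription", x$prescription, "Gy):\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("\nfinal objective %.6g in %d iterations; %d dwell(s) at the lower bound; normalization factor %.4f\n",
              x$objective_value, x$n_iter, length(x$active_bound),
              x$normalization_factor))
  invisible(x)
}

#' @export
coef.hdrplan <- function(object, ...) {
  nm <- unlist(lapply(object$channels, function(ch)
    paste0(ch$name, ".", seq_len(nrow(ch$dwell_positions)))), use.names = FALSE)
  stats::setNames(object$times, nm)
}

#' @export
fitted.hdrplan <- function(object, ...) object$doses

#' Predict dose at arbitrary points
#'
#' @param object an [hdrplan()] fit.
#' @param newpoints n x 3 coordinate matrix, cm; defaults to the fit's own
#'   calculation points.
#' @param ... unused.
#' @return dose vector, Gy (normalized plan).
#' @export
predict.hdrplan <- function(object, newpoints = NULL, ...) {
  if (is.null(newpoints)) return(object$doses)
  k <- build_dose_kernel(object$source, object$channels, newpoints)
  total_dose(k, object$times)
}

#' @export
residuals.hdrplan <- function(object, ...) {
  # signed violation per calculation point: negative = target underdose,
  # positive = OAR overdose; zero where the objectives are met
  res <- numeric(length(object$doses))
  spec <- object$objectives
  for (i in seq_len(nrow(spec))) {
    idx <- object$points$roi_membership[[spec$roi[i]]]
    d <- object$doses[idx]
    if (!is.na(spec$min_dose_gy[i])) {
      v <- d < spec$min_dose_gy[i]
      res[idx[v]] <- res[idx[v]] + (d[v] - spec$min_dose_gy[i])
    }
    if (!is.na(spec$max_dose_gy[i])) {
      v <- d > spec$max_dose_gy[i]
      res[idx[v]] <- res[idx[v]] + (d[v] - spec$max_dose_gy[i])
    }
  }
  res
}

#' Plot an inverse plan fit
#'
#' `type = "trace"` draws the objective value across accepted iterations
#' (log y); `type = "dvh"` draws the cumulative DVH of every ROI with the
#' prescription marked.
#'
#' @param x an [hdrplan()] fit.
#' @param type `"trace"` or `"dvh"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.hdrplan <- function(x, type = c("dvh", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "l", log = "y",
                   xlab = "accepted iteration", ylab = "objective F", ...)
    return(invisible(x))
  }
  rois <- names(x$points$roi_membership)
  cols <- grDevices::hcl.colors(length(rois), "Dark 2")
  xmax <- max(x$doses)
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 100),
                 xlab = "dose [Gy]", ylab = "volume [%]", ...)
  for (i in seq_along(rois)) {
    d <- sort(x$doses[x$points$roi_membership[[rois[i]]]])
    vol <- 100 * rev(seq_along(d)) / length(d)
    graphics::lines(d, vol, col = cols[i], lwd = 2)
  }
  graphics::abline(v = x$prescription, lty = 3)
  graphics::legend("topright", legend = rois, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
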