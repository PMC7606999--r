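#' Read an objective specification file
#'
#' Structured JSON mirroring the prescription table: a `rois` array with
#' fields `roi`, `role`, `min_dose_gy`, `min_weight`, `max_dose_gy`,
#' `max_weight` (null = absent), and an optional `optimizer` block with
#' `dtmf`, `max_iterations`, `lower_bound`, `initial_time`.
#'
#' @param path JSON file path.
#' @return list with `objectives` (an [objective_spec()]) and `config`
#'   (an [optimizer_config()], defaults filled in).
#' @export
read_objectives_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("objectives file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rois)) abort_config("objectives file has no `rois` array")
  df <- as.data.frame(obj$rois)
  for (col in c("min_dose_gy", "min_weight", "max_dose_gy", "max_weight"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  opt <- obj$optimizer
  cfg <- optimizer_config(
    dtmf = if (is.null(opt$dtmf)) 10 else opt$dtmf,
    max_iterations = if (is.null(opt$max_iterations)) 100L else opt$max_iterations,
    lower_bound = if (is.null(opt$lower_bound)) 1e-6 else opt$lower_bound,
    initial_time = if (is.null(opt$initial_time)) 1.0 else opt$initial_time
  )
  list(objectives = objective_spec(df), config = cfg)
}

#' Read a run configuration file
#'
#' JSON with blocks: `paths` (`source_csv`, `phantom`, `objectives`,
#' `output_dir`), optional `optimizer` overrides, `sampling` (`fraction`,
#' `seed`) and `prescription` (Gy, default 6).
#'
#' @param path JSON file path.
#' @return the parsed configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$paths)) abort_config("run config has no `paths` block")
  cfg
}

# resolve a config (path or list) into loaded inputs
.load_run_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  p <- config$paths
  for (key in c("phantom", "objectives", "output_dir"))
    if (is.null(p[[key]])) abort_config(sprintf("run config paths block missing `%s`", key))
  source <- if (is.null(p$source_csv)) fixture_source() else read_source_csv(p$source_csv)
  phantom <- read_phantom_json(p$phantom)
  spec <- read_objectives_json(p$objectives)
  cfg <- spec$config
  for (key in c("dtmf", "max_iterations", "lower_bound", "initial_time"))
    if (!is.null(config$optimizer[[key]])) cfg[[key]] <- config$optimizer[[key]]
  cfg <- optimizer_config(cfg$dtmf, cfg$max_iterations, cfg$lower_bound, cfg$initial_time)
  sampling <- list(
    fraction = if (is.null(config$sampling$fraction)) 1 else config$sampling$fraction,
    seed = if (is.null(config$sampling$seed)) 1L else as.integer(config$sampling$seed))
  prescription <- if (is.null(config$prescription)) 6.0 else config$prescription
  list(config = config, source = source, phantom = phantom,
       objectives = spec$objectives, optimizer = cfg,
       sampling = sampling, prescription = prescription,
       output_dir = p$output_dir)
}

.write_manifest <- function(path, inputs, extra = list()) {
  cfg <- inputs$config
  manifest <- c(list(
    package = "hdrplan",
    version = as.character(utils::packageVersion("hdrplan")),
    paths = cfg$paths,
    optimizer = unclass(inputs$optimizer),
    sampling = inputs$sampling,
    prescription = inputs$prescription
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the optimize pipeline
#'
#' Full sample / kernel / optimize / normalize / report pipeline from a run
#' configuration (path or parsed list). Writes four artifacts to the output
#' directory: `plan.csv`, `dvh_report.csv`, `objective_trace.csv` and
#' `manifest.json`. Deterministic: identical configurations produce
#' byte-identical plan CSVs.
#'
#' @param config run configuration path or list (see [read_run_config()]).
#' @param verbose print the per-iteration objective trace.
#' @return named character vector of artifact paths, invisibly.
#' @export
run_optimize <- function(config, verbose = FALSE) {
  inputs <- .load_run_inputs(config)
  dir.create(inputs$output_dir, recursive = TRUE, showWarnings = FALSE)

  fit <- hdrplan(inputs$phantom, inputs$objectives, source = inputs$source,
                 config = inputs$optimizer, prescription = inputs$prescription,
                 subsample_fraction = inputs$sampling$fraction,
                 sampling_seed = inputs$sampling$seed)
  if (verbose)
    message(paste(sprintf("iter %3d  F = %.8g", seq_along(fit$trace) - 1L, fit$trace),
                  collapse = "\n"))

  out <- file.path(inputs$output_dir,
                   c(plan = "plan.csv", report = "dvh_report.csv",
                     trace = "objective_trace.csv", manifest = "manifest.json"))
  names(out) <- c("plan", "report", "trace", "manifest")

  pl <- unflatten_times(plan(inputs$phantom$channels), fit$times)
  write_plan_csv(pl, out["plan"])
  rep_df <- fit$report
  rep_df$value <- sprintf("%.12g", rep_df$value)
  utils::write.csv(rep_df, out["report"], row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(iteration = seq_along(fit$trace) - 1L,
               objective = sprintf("%.17g", fit$trace)),
    out["trace"], row.names = FALSE, quote = FALSE)
  .write_manifest(out["manifest"], inputs, extra = list(
    normalization_factor = fit$normalization_factor,
    final_objective = fit$objective_value,
    iterations = fit$n_iter))
  invisible(out)
}

#' Run the modulation-factor sweep pipeline
#'
#' One full optimization per modulation-factor value on identical inputs;
#' writes `dtmf_sweep.csv` (columns `dtmf,dtsd_s`) and a manifest.
#'
#' @param config run configuration path or list.
#' @param dtmf_values nonnegative factors, >= 2 values.
#' @param verbose log the final objective per value.
#' @return named artifact paths, invisibly.
#' @export
run_sweep <- function(config, dtmf_values, verbose = FALSE) {
  if (length(dtmf_values) < 2L) abort_input("need >= 2 modulation factor values")
  inputs <- .load_run_inputs(config)
  dir.create(inputs$output_dir, recursive = TRUE, showWarnings = FALSE)
  points <- sample_calc_points(inputs$phantom$rois, inputs$sampling$fraction,
                               inputs$sampling$seed)
  kernel <- build_dose_kernel(inputs$source, inputs$phantom$channels, points)
  sweep <- dtmf_sweep(kernel, points, inputs$objectives, dtmf_values,
                      inputs$optimizer)
  if (verbose)
    message(paste(sprintf("dtmf %-6g  F = %.8g  dtsd = %.6g s",
                          sweep$dtmf, sweep$objective, sweep$dtsd_s),
                  collapse = "\n"))
  out <- file.path(inputs$output_dir, c(sweep = "dtmf_sweep.csv",
                                        manifest = "sweep_manifest.json"))
  names(out) <- c("sweep", "manifest")
  utils::write.csv(
    data.frame(dtmf = sweep$dtmf, dtsd_s = sprintf("%.12g", sweep$dtsd_s)),
    out["sweep"], row.names = FALSE, quote = FALSE)
  .write_manifest(out["manifest"], inputs, extra = list(dtmf_values = dtmf_values))
  invisible(out)
}

#' Recompute a DVH report from a stored plan
#'
#' Reads a dwell-time plan CSV, recomputes doses on the phantom's
#' calculation points with the same sampling settings, and writes the DVH
#' quality report. With the sampling settings of the optimize run this
#' reproduces its report exactly.
#'
#' @param plan_csv plan CSV path.
#' @param phantom phantom list or path to a phantom JSON.
#' @param source a [source_model()] (default: packaged synthetic source).
#' @param prescription Gy.
#' @param out output CSV path, or NULL to skip writing.
#' @param fraction,seed calculation-point sampling settings.
#' @return the report data.frame, invisibly if `out` is given.
#' @export
run_report <- function(plan_csv, phantom, source = fixture_source(),
                       prescription = 6.0, out = NULL,
                       fraction = 1, seed = 1L) {
  pl <- read_plan_csv(plan_csv)
  if (is.character(phantom)) phantom <- read_phantom_json(phantom)
  geo <- stack_dwell_positions(phantom$channels)
  geo2 <- stack_dwell_positions(pl$channels)
  if (nrow(geo) != nrow(geo2) || max(abs(geo - geo2)) > 1e-6)
    abort_input("plan dwell positions do not match the phantom's channels")
  points <- sample_calc_points(phantom$rois, fraction, seed)
  kernel <- build_dose_kernel(source, phantom$channels, points)
  doses <- total_dose(kernel, flatten_times(pl))
  report <- plan_quality_report(doses, points, prescription,
                                times = flatten_times(pl))
  if (!is.null(out)) {
    rep_df <- report
    rep_df$value <- sprintf("%.12g", rep_df$value)
    utils::write.csv(rep_df, out, row.names = FALSE, quote = FALSE)
    return(invisible(report))
  }
  report
}

#' Generate and store a phantom
#'
#' @param kind applicator kind (see [phantom_spec()]).
#' @param out output JSON path.
#' @param target_volume,spacing,margin,seed passed to [phantom_spec()].
#' @return `out`, invisibly.
#' @export
run_make_phantom <- function(kind, out, target_volume = 52.65,
                             spacing = 0.1, margin = 0.3, seed = 1L) {
  ph <- make_phantom(phantom_spec(kind, target_volume, spacing, margin, seed))
  write_phantom_json(ph, out)
}
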