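#' TG-43 point-source model
#'
#' Bundles the physical characterization of an HDR source in the 1D
#' (point-source) TG-43 formalism: the dose-rate constant \eqn{\Lambda}, the
#' air-kerma strength \eqn{S_K}, and tabulated radial dose function
#' \eqn{g(r)} and 1D anisotropy factor \eqn{\phi_{an}(r)}. The dose rate at
#' distance r (cm) from the source is
#' \deqn{\dot D(r) = S_K \Lambda (r_0/r)^2 g(r) \phi_{an}(r)}
#' in Gy/h, with \eqn{r_0 = 1} cm the reference radius. Distances are clamped
#' to `[r_min, r_max]` before table lookup: below `r_min` the voxel grid
#' cannot resolve the dose anyway, and beyond `r_max` the tables end.
#'
#' @param dose_rate_constant \eqn{\Lambda}, Gy h^-1 U^-1.
#' @param air_kerma_strength \eqn{S_K}, U (1 U = 1 cGy cm^2 h^-1).
#' @param radial_dose_table data.frame with columns `r_cm`, `g`;
#'   strictly increasing in `r_cm`, `g(1) = 1` by normalization.
#' @param anisotropy_table data.frame with columns `r_cm`, `phi_an`;
#'   strictly increasing in `r_cm`.
#' @param r_min,r_max near-source clamp and table extent, cm.
#' @param reference_radius TG-43 reference radius \eqn{r_0}, cm (default 1).
#' @return An object of class `source_model`.
#' @seealso [dose_rate_at_point()], [build_dose_kernel()], [read_source_csv()]
#' @export
source_model <- function(dose_rate_constant, air_kerma_strength,
                         radial_dose_table, anisotropy_table,
                         r_min = 0.1, r_max = 10, reference_radius = 1.0) {
  stopifnot_number(dose_rate_constant, "dose_rate_constant", positive = TRUE)
  stopifnot_number(air_kerma_strength, "air_kerma_strength", positive = TRUE)
  stopifnot_number(r_min, "r_min", positive = TRUE)
  stopifnot_number(r_max, "r_max", positive = TRUE)
  if (r_max <= r_min) abort_config("`r_max` must exceed `r_min`")

  check_table <- function(tab, value_col, label) {
    if (!is.data.frame(tab) || nrow(tab) == 0L)
      abort_config(sprintf("%s table is empty or not a data.frame", label))
    if (!all(c("r_cm", value_col) %in% names(tab)))
      abort_config(sprintf("%s table must have columns r_cm and %s", label, value_col))
    r <- tab$r_cm; v <- tab[[value_col]]
    if (anyNA(r) || anyNA(v) || !all(is.finite(r)) || !all(is.finite(v)))
      abort_config(sprintf("%s table contains non-finite entries", label))
    if (nrow(tab) > 1L && any(diff(r) <= 0))
      abort_config(sprintf("%s table radii must be strictly increasing", label))
    if (any(v <= 0))
      abort_config(sprintf("%s table values must be positive", label))
    tab[, c("r_cm", value_col)]
  }
  radial_dose_table <- check_table(radial_dose_table, "g", "radial dose")
  anisotropy_table  <- check_table(anisotropy_table, "phi_an", "anisotropy")

  obj <- structure(list(
    dose_rate_constant = dose_rate_constant,
    air_kerma_strength = air_kerma_strength,
    radial_dose_table  = radial_dose_table,
    anisotropy_table   = anisotropy_table,
    r_min = r_min, r_max = r_max,
    reference_radius = reference_radius
  ), class = "source_model")

  g0 <- radial_dose(obj, reference_radius)
  if (abs(g0 - 1) > 1e-6)
    abort_config(sprintf("radial dose function is not normalized: g(r0) = %.8f", g0))
  obj
}

# shared clamp-and-interpolate lookup (linear in r, flat beyond table ends)
.table_lookup <- function(source, tab, value_col, r) {
  if (any(!is.finite(r)) || any(r <= 0)) abort_input("radii must be finite and > 0")
  if (is.null(tab) || nrow(tab) == 0L) abort_config("lookup table is empty")
  r <- pmin(pmax(r, source$r_min), source$r_max)
  if (nrow(tab) == 1L) return(rep(tab[[value_col]], length(r)))
  stats::approx(tab$r_cm, tab[[value_col]], xout = r, rule = 2)$y
}

#' Radial dose function g(r)
#'
#' Linear interpolation on the source's radial dose table; `r` is clamped to
#' `[r_min, r_max]` before lookup.
#'
#' @param source a [source_model()].
#' @param r radial distance(s), cm; must be > 0.
#' @return dimensionless g(r), vectorized over `r`.
#' @export
radial_dose <- function(source, r) {
  .table_lookup(source, source$radial_dose_table, "g", r)
}

#' 1D anisotropy factor phi_an(r)
#'
#' Same lookup contract as [radial_dose()].
#'
#' @inheritParams radial_dose
#' @return dimensionless phi_an(r), vectorized over `r`.
#' @export
anisotropy <- function(source, r) {
  .table_lookup(source, source$anisotropy_table, "phi_an", r)
}

# dose rate in Gy per SECOND at radial distance r (cm); vectorized, clamped.
# The per-hour TG-43 product is converted once here (3600 s/h).
.dose_rate_r <- function(source, r) {
  r <- pmax(r, source$r_min)
  rc <- pmin(r, source$r_max)  # table clamp; inverse square still uses r_min-clamped r
  source$air_kerma_strength * source$dose_rate_constant *
    (source$reference_radius / r)^2 *
    .table_lookup(source, source$radial_dose_table, "g", rc) *
    .table_lookup(source, source$anisotropy_table, "phi_an", rc) / 3600
}

#' Dose rate at a point from a single dwell position
#'
#' TG-43 point-source dose rate, per unit dwell time, from a source dwelling
#' at `dwell_position` to `calc_point`. The source-to-point distance is
#' clamped below at `r_min`, so a calculation point coincident with a dwell
#' position yields a large but finite value.
#'
#' @param source a [source_model()].
#' @param dwell_position,calc_point numeric length-3 Cartesian coordinates, cm.
#' @return dose rate, Gy per second of dwell time.
#' @export
dose_rate_at_point <- function(source, dwell_position, calc_point) {
  dwell_position <- as.numeric(dwell_position)
  calc_point <- as.numeric(calc_point)
  if (length(dwell_position) != 3L || length(calc_point) != 3L)
    abort_input("positions must be length-3 coordinate vectors")
  if (any(!is.finite(dwell_position)) || any(!is.finite(calc_point)))
    abort_input("positions must have finite coordinates")
  .dose_rate_r(source, sqrt(sum((dwell_position - calc_point)^2)))
}

#' @export
print.source_model <- function(x, ...) {
  cat("TG-43 point-source model\n")
  cat(sprintf("  Lambda: %.5g Gy/h/U   S_K: %.5g U\n",
              x$dose_rate_constant, x$air_kerma_strength))
  cat(sprintf("  g(r): %d nodes on [%.3g, %.3g] cm; phi_an(r): %d nodes\n",
              nrow(x$radial_dose_table), min(x$radial_dose_table$r_cm),
              max(x$radial_dose_table$r_cm), nrow(x$anisotropy_table)))
  cat(sprintf("  clamp: r in [%.3g, %.3g] cm\n", x$r_min, x$r_max))
  invisible(x)
}

#' Read a source characterization CSV
#'
#' The file format is a plain-text CSV with a `key,value` header block
#' (keys `dose_rate_constant`, `air_kerma_strength`, `r_min`, `r_max`)
#' followed by two column groups introduced by the exact header lines
#' `r_cm,g` and `r_cm,phi_an`.
#'
#' @param path file path.
#' @return a [source_model()].
#' @export
read_source_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("source CSV not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ig <- match("r_cm,g", lines)
  ip <- match("r_cm,phi_an", lines)
  if (is.na(ig) || is.na(ip) || ip <= ig)
    abort_config("source CSV must contain an `r_cm,g` block followed by `r_cm,phi_an`")

  head_block <- lines[seq_len(ig - 1L)]
  head_block <- head_block[head_block != "key,value"]
  kv <- do.call(rbind, strsplit(head_block, ","))
  keys <- kv[, 1]; vals <- suppressWarnings(as.numeric(kv[, 2]))
  need <- c("dose_rate_constant", "air_kerma_strength", "r_min", "r_max")
  if (!all(need %in% keys)) abort_config(
    sprintf("source CSV header block missing keys: %s",
            paste(setdiff(need, keys), collapse = ", ")))
  getv <- function(k) vals[match(k, keys)]

  parse_block <- function(rows, cols) {
    if (length(rows) == 0L) abort_config("empty table block in source CSV")
    m <- do.call(rbind, strsplit(rows, ","))
    out <- data.frame(as.numeric(m[, 1]), as.numeric(m[, 2]))
    names(out) <- cols
    out
  }
  gtab <- parse_block(lines[seq.int(ig + 1L, ip - 1L)], c("r_cm", "g"))
  ptab <- parse_block(lines[seq.int(ip + 1L, length(lines))], c("r_cm", "phi_an"))

  source_model(
    dose_rate_constant = getv("dose_rate_constant"),
    air_kerma_strength = getv("air_kerma_strength"),
    radial_dose_table = gtab, anisotropy_table = ptab,
    r_min = getv("r_min"), r_max = getv("r_max")
  )
}

#' Write a source characterization CSV
#'
#' Inverse of [read_source_csv()]; round-trips a [source_model()] exactly
#' (coordinates written at full precision).
#'
#' @param source a [source_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_source_csv <- function(source, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "key,value",
    paste0("dose_rate_constant,", num(source$dose_rate_constant)),
    paste0("air_kerma_strength,", num(source$air_kerma_strength)),
    paste0("r_min,", num(source$r_min)),
    paste0("r_max,", num(source$r_max)),
    "r_cm,g",
    paste0(num(source$radial_dose_table$r_cm), ",", num(source$radial_dose_table$g)),
    "r_cm,phi_an",
    paste0(num(source$anisotropy_table$r_cm), ",", num(source$anisotropy_table$phi_an))
  )
  writeLines(lines, path)
  invisible(path)
}
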