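#' Build the dose kernel matrix
#'
#' Assembles the matrix \eqn{d_{m,n,i}} of dose rate (Gy/s) delivered to each
#' calculation point i per unit dwell time at each dwell position (m, n).
#' Total dose is then the linear superposition
#' \deqn{D_i = \sum_m \sum_n d_{m,n,i} \, t_{m,n}.}
#' Columns are ordered in (channel, position) order, matching
#' [flatten_times()].
#'
#' @param source a [source_model()].
#' @param channels list of [channel()] objects (>= 1 dwell each).
#' @param points a [sample_calc_points()] result, or an n x 3 coordinate
#'   matrix in cm.
#' @return An object of class `dose_kernel`: list with `values`
#'   (points x dwells matrix, Gy/s), `point_count`, `dwell_count`,
#'   `dwell_index_map` (data.frame `channel`, `position`), and
#'   `channel_index` (integer per column).
#' @export
build_dose_kernel <- function(source, channels, points) {
  if (!is.list(channels) || length(channels) == 0L)
    abort_input("need at least one channel")
  P <- if (inherits(points, "calc_points")) points$points else as.matrix(points)
  if (nrow(P) < 1L || ncol(P) != 3L) abort_input("need >= 1 calculation point (x,y,z)")
  if (any(!is.finite(P))) abort_input("calculation points must be finite")

  W <- stack_dwell_positions(channels)
  k <- nrow(W)
  values <- matrix(0, nrow = nrow(P), ncol = k)
  for (j in seq_len(k)) {
    r <- sqrt((P[, 1] - W[j, 1])^2 + (P[, 2] - W[j, 2])^2 + (P[, 3] - W[j, 3])^2)
    values[, j] <- .dose_rate_r(source, r)
  }

  lens <- vapply(channels, function(ch) nrow(ch$dwell_positions), 0L)
  map <- data.frame(channel = rep(seq_along(channels), lens),
                    position = unlist(lapply(lens, seq_len), use.names = FALSE))
  structure(list(values = values,
                 point_count = nrow(P),
                 dwell_count = k,
                 dwell_index_map = map,
                 channel_index = map$channel),
            class = "dose_kernel")
}

#' Total dose by superposition
#'
#' \eqn{D_i = \sum_{m,n} d_{m,n,i} t_{m,n}}; linear in the dwell times.
#'
#' @param kernel a [build_dose_kernel()] result.
#' @param times flat dwell time vector, seconds, in kernel column order.
#' @return dose vector, Gy, one entry per calculation point.
#' @export
total_dose <- function(kernel, times) {
  if (length(times) != kernel$dwell_count)
    abort_input("`times` length must equal the kernel dwell count")
  if (any(times < 0)) abort_input("dwell times must be >= 0")
  drop(kernel$values %*% times)
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat(sprintf("dose kernel: %d calculation points x %d dwells (%d channels)\n",
              x$point_count, x$dwell_count, max(x$channel_index)))
  invisible(x)
}
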