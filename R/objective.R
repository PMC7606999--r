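#' Dose objectives per region of interest
#'
#' One row per ROI, mirroring the usual inverse-planning prescription table:
#' a minimum-dose objective (dose `min_dose_gy`, weight `min_weight`) and/or
#' a maximum-dose objective (`max_dose_gy`, `max_weight`). Targets must carry
#' a minimum objective; organs at risk must carry a maximum objective; an ROI
#' may carry both.
#'
#' @param df data.frame with columns `roi`, `role` ("target"/"oar"),
#'   `min_dose_gy`, `min_weight`, `max_dose_gy`, `max_weight` (NA = absent).
#' @return An object of class `objective_spec` (a validated data.frame).
#' @export
objective_spec <- function(df) {
  need <- c("roi", "role", "min_dose_gy", "min_weight", "max_dose_gy", "max_weight")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    abort_input(sprintf("objective spec needs columns: %s", paste(need, collapse = ", ")))
  df <- df[, need]
  df$role <- as.character(df$role)
  if (!all(df$role %in% c("target", "oar")))
    abort_input("role must be 'target' or 'oar'")
  has_min <- !is.na(df$min_dose_gy)
  has_max <- !is.na(df$max_dose_gy)
  if (any(df$role == "target" & !has_min))
    abort_input("every target ROI needs a minimum-dose objective")
  if (any(df$role == "oar" & !has_max))
    abort_input("every OAR needs a maximum-dose objective")
  if (any(has_min & (is.na(df$min_weight) | df$min_weight < 0)) ||
      any(has_max & (is.na(df$max_weight) | df$max_weight < 0)))
    abort_input("objective weights must be present and >= 0")
  if (any(df$min_dose_gy[has_min] <= 0) || any(df$max_dose_gy[has_max] <= 0))
    abort_input("objective doses must be > 0")
  class(df) <- c("objective_spec", "data.frame")
  df
}

#' Optimizer settings
#'
#' @param dtmf dwell time modulation factor `p_SOU` (>= 0): the weight of the
#'   per-channel minimum-anchored dwell-time variance penalty. Default 10.
#' @param max_iterations outer quasi-Newton iteration cap (default 100).
#' @param lower_bound box lower bound on every dwell time, seconds
#'   (default 1e-6); keeps times strictly positive during optimization.
#' @param initial_time starting dwell time at every position, seconds
#'   (default 1).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(dtmf = 10, max_iterations = 100L,
                             lower_bound = 1e-6, initial_time = 1.0) {
  stopifnot_number(dtmf, "dtmf", nonneg = TRUE)
  stopifnot_number(lower_bound, "lower_bound", positive = TRUE)
  stopifnot_number(initial_time, "initial_time")
  if (initial_time < lower_bound) abort_input("`initial_time` must be >= `lower_bound`")
  if (!is_number(max_iterations) || max_iterations < 1)
    abort_input("`max_iterations` must be >= 1")
  structure(list(dtmf = dtmf, max_iterations = as.integer(max_iterations),
                 lower_bound = lower_bound, initial_time = initial_time),
            class = "optimizer_config")
}

#' One-sided quadratic penalty for one ROI
#'
#' For a minimum-dose objective the penalty is
#' \eqn{p \sum_i H(D_0 - D_i)(D_i - D_0)^2} summed over voxels with
#' \eqn{D_i \le D_0} (underdosed target voxels); for a maximum-dose objective
#' the Heaviside switch reverses and voxels with \eqn{D_i \ge D_0} are
#' penalized. At exact equality the switch is on but the squared term
#' vanishes, so the choice is value- and gradient-neutral.
#'
#' @param doses Gy vector for the ROI's calculation points.
#' @param min_dose_gy,min_weight minimum objective (NA to omit).
#' @param max_dose_gy,max_weight maximum objective (NA to omit).
#' @return scalar objective contribution (weighted Gy^2).
#' @export
roi_penalty <- function(doses, min_dose_gy = NA, min_weight = NA,
                        max_dose_gy = NA, max_weight = NA) {
  if (any(!is.finite(doses)) || any(doses < 0))
    abort_input("doses must be finite and >= 0")
  f <- 0
  if (!is.na(min_dose_gy)) {
    dev <- doses[doses <= min_dose_gy] - min_dose_gy
    f <- f + min_weight * sum(dev^2)
  }
  if (!is.na(max_dose_gy)) {
    dev <- doses[doses >= max_dose_gy] - max_dose_gy
    f <- f + max_weight * sum(dev^2)
  }
  f
}

#' Dwell-time modulation penalty
#'
#' The variance-restriction term
#' \deqn{p_{SOU} \sum_m \frac{1}{N_m} \sum_n (t_{m,n} - t_{m,min})^2,}
#' anchored at each channel's *minimum* dwell time rather than the mean:
#' large dwell times are pulled down toward the channel minimum, while a
#' short dwell (a position unsuited to dwelling because of a nearby organ at
#' risk) is retained rather than inflated.
#'
#' @param times flat dwell time vector, seconds.
#' @param channel_index integer channel id per entry of `times`.
#' @param p_sou modulation factor (>= 0), dimensionless.
#' @return scalar objective contribution.
#' @export
dtmf_term <- function(times, channel_index, p_sou) {
  if (p_sou == 0) return(0)
  total <- 0
  for (m in unique(channel_index)) {
    t <- times[channel_index == m]
    total <- total + sum((t - min(t))^2) / length(t)
  }
  p_sou * total
}

# gradient of dtmf_term w.r.t. times; argmin frozen at the evaluation point
# (first occurrence wins ties), including the coupling through t_{m,min}.
dtmf_gradient <- function(times, channel_index, p_sou) {
  g <- numeric(length(times))
  if (p_sou == 0) return(g)
  for (m in unique(channel_index)) {
    idx <- which(channel_index == m)
    t <- times[idx]
    n <- length(t)
    k <- which.min(t)
    dev <- t - t[k]
    gm <- (2 * p_sou / n) * dev
    gm[k] <- -(2 * p_sou / n) * sum(dev)
    g[idx] <- gm
  }
  g
}

#' Objective function value
#'
#' The full inverse-planning objective: one-sided quadratic dose penalties
#' over every ROI's calculation points plus the dwell-time modulation term,
#' \deqn{F(t) = \sum_{ROI} \sum_{i \in ROI} p \, H \, (D_i - D_0)^2 +
#'   p_{SOU} \sum_m \frac{1}{N_m} \sum_n (t_{m,n} - t_{m,min})^2.}
#' F is nonnegative, and zero exactly when every voxel meets its objectives
#' and (for `p_SOU > 0`) dwell times are uniform within each channel.
#'
#' @param times flat dwell time vector, seconds.
#' @param kernel a [build_dose_kernel()] result.
#' @param points the matching [sample_calc_points()] result.
#' @param spec an [objective_spec()].
#' @param config an [optimizer_config()] (supplies `dtmf`).
#' @return scalar F >= 0.
#' @export
objective_value <- function(times, kernel, points, spec, config) {
  doses <- total_dose(kernel, times)
  f <- 0
  for (i in seq_len(nrow(spec))) {
    idx <- points$roi_membership[[spec$roi[i]]]
    if (is.null(idx)) abort_input(sprintf("ROI '%s' not present in calc points", spec$roi[i]))
    f <- f + roi_penalty(doses[idx],
                         spec$min_dose_gy[i], spec$min_weight[i],
                         spec$max_dose_gy[i], spec$max_weight[i])
  }
  f + dtmf_term(times, kernel$channel_index, config$dtmf)
}

#' Analytic objective gradient
#'
#' Exact derivative of [objective_value()]: each violated voxel contributes
#' \eqn{2 p (D_i - D_0) d_{m,n,i}} to every dwell's component, and the
#' modulation term is differentiated with the per-channel argmin frozen at
#' the evaluation point (the minimizing index additionally carries the
#' coupling through \eqn{t_{m,min}}). Exact almost everywhere; the Heaviside
#' switching surfaces and within-channel minimum ties form a measure-zero
#' set on which the squared terms vanish anyway.
#'
#' @inheritParams objective_value
#' @return gradient vector, one entry per dwell.
#' @export
objective_gradient <- function(times, kernel, points, spec, config) {
  doses <- total_dose(kernel, times)
  coef <- numeric(kernel$point_count)
  for (i in seq_len(nrow(spec))) {
    idx <- points$roi_membership[[spec$roi[i]]]
    if (is.null(idx)) abort_input(sprintf("ROI '%s' not present in calc points", spec$roi[i]))
    d <- doses[idx]
    if (!is.na(spec$min_dose_gy[i])) {
      viol <- d <= spec$min_dose_gy[i]
      coef[idx[viol]] <- coef[idx[viol]] +
        2 * spec$min_weight[i] * (d[viol] - spec$min_dose_gy[i])
    }
    if (!is.na(spec$max_dose_gy[i])) {
      viol <- d >= spec$max_dose_gy[i]
      coef[idx[viol]] <- coef[idx[viol]] +
        2 * spec$max_weight[i] * (d[viol] - spec$max_dose_gy[i])
    }
  }
  drop(crossprod(kernel$values, coef)) +
    dtmf_gradient(times, kernel$channel_index, config$dtmf)
}
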