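#' Applicator channel
#'
#' One applicator tube or needle through which the stepping source travels,
#' holding an ordered list of 3D dwell positions. Positions generated by the
#' phantom module are spaced `step` cm apart along the channel (0.25 cm by
#' default, the usual HDR afterloader step); spacing is not enforced on
#' imported geometries.
#'
#' @param name channel label.
#' @param dwell_positions numeric matrix, one row per dwell position,
#'   columns x/y/z in cm.
#' @param step nominal source step size, cm.
#' @return An object of class `channel`.
#' @export
channel <- function(name, dwell_positions, step = 0.25) {
  dwell_positions <- as.matrix(dwell_positions)
  if (nrow(dwell_positions) < 1L || ncol(dwell_positions) != 3L)
    abort_input("a channel needs >= 1 dwell position with 3 coordinates")
  if (any(!is.finite(dwell_positions)))
    abort_input("dwell positions must be finite")
  stopifnot_number(step, "step", positive = TRUE)
  dimnames(dwell_positions) <- list(NULL, c("x", "y", "z"))
  structure(list(name = as.character(name),
                 dwell_positions = dwell_positions,
                 step = step),
            class = "channel")
}

n_dwells <- function(channels) sum(vapply(channels, function(ch) nrow(ch$dwell_positions), 0L))

#' Treatment plan: channels plus dwell times
#'
#' @param channels list of [channel()] objects.
#' @param dwell_times list of per-channel numeric vectors (seconds), one entry
#'   per dwell position; defaults to all zero.
#' @return An object of class `plan`.
#' @export
plan <- function(channels, dwell_times = NULL) {
  if (!is.list(channels) || length(channels) == 0L)
    abort_input("`channels` must be a non-empty list of channel objects")
  lens <- vapply(channels, function(ch) nrow(ch$dwell_positions), 0L)
  if (is.null(dwell_times)) dwell_times <- lapply(lens, numeric)
  if (length(dwell_times) != length(channels) ||
      !all(lengths(dwell_times) == lens))
    abort_input("`dwell_times` shape must match the channels")
  if (any(unlist(dwell_times) < 0)) abort_input("dwell times must be >= 0")
  structure(list(channels = channels, dwell_times = dwell_times), class = "plan")
}

#' Flatten per-channel dwell times to a single vector
#'
#' Concatenates in (channel, position) order — the same ordering used by the
#' dose kernel's dwell index map. [unflatten_times()] is its inverse.
#'
#' @param plan a [plan()].
#' @return numeric vector of length equal to the total dwell count.
#' @export
flatten_times <- function(plan) unlist(plan$dwell_times, use.names = FALSE)

#' @rdname flatten_times
#' @param times flat numeric vector in (channel, position) order.
#' @return for `unflatten_times`, a [plan()] with the times distributed back
#'   over channels.
#' @export
unflatten_times <- function(plan, times) {
  lens <- vapply(plan$channels, function(ch) nrow(ch$dwell_positions), 0L)
  if (length(times) != sum(lens)) abort_input("`times` length mismatch")
  idx <- rep(seq_along(lens), lens)
  plan$dwell_times <- split(as.numeric(times), idx)
  names(plan$dwell_times) <- NULL
  plan
}

# channel index (m) for each flattened dwell, in flatten_times() order
channel_index_of <- function(channels) {
  lens <- vapply(channels, function(ch) nrow(ch$dwell_positions), 0L)
  rep(seq_along(channels), lens)
}

# all dwell positions stacked in flatten order
stack_dwell_positions <- function(channels) {
  do.call(rbind, lapply(channels, function(ch) ch$dwell_positions))
}

#' Voxelized region of interest mask
#'
#' A boolean occupancy volume on a regular axis-aligned grid. A voxel is
#' occupied when its center lies inside the structure; the voxel at index
#' (i, j, k) (1-based) has its center at `origin + (index - 0.5) * spacing`.
#'
#' @param name ROI label.
#' @param role `"target"` or `"oar"`.
#' @param grid list with `origin` (length-3, cm), `spacing` (length-3, cm),
#'   `dims` (length-3 integer).
#' @param occupancy logical array with dimensions `grid$dims`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, role, grid, occupancy) {
  role <- match.arg(role, c("target", "oar"))
  if (!all(c("origin", "spacing", "dims") %in% names(grid)))
    abort_input("grid must have origin, spacing, dims")
  if (any(grid$spacing <= 0)) abort_input("grid spacing must be > 0 on each axis")
  occupancy <- array(as.logical(occupancy), dim = grid$dims)
  if (!any(occupancy)) abort_input(sprintf("ROI '%s' has no occupied voxels", name))
  structure(list(name = as.character(name), role = role,
                 grid = list(origin = as.numeric(grid$origin),
                             spacing = as.numeric(grid$spacing),
                             dims = as.integer(grid$dims)),
                 occupancy = occupancy),
            class = "roi_mask")
}

#' ROI volume in cm^3
#'
#' Occupied voxel count times the voxel volume.
#'
#' @param roi a [roi_mask()].
#' @return volume, cm^3.
#' @export
roi_volume <- function(roi) {
  sum(roi$occupancy) * prod(roi$grid$spacing)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    identical(a$dims, b$dims)
}

# centers of occupied voxels of one mask, n x 3 matrix
voxel_centers <- function(roi) {
  idx <- which(roi$occupancy, arr.ind = TRUE)
  sweep(sweep(idx - 0.5, 2, roi$grid$spacing, `*`), 2, roi$grid$origin, `+`)
}

# run a block with a private RNG stream, leaving the caller's stream intact
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample dose calculation points from ROI masks
#'
#' Takes the voxel centers of each ROI's occupied voxels as calculation
#' points. With `fraction < 1` a seeded uniform subsample of
#' `round(fraction * n_occupied)` voxels is drawn per ROI, which shrinks the
#' dose kernel proportionally; `fraction = 1` is exhaustive and ignores the
#' seed. A voxel belonging to several ROIs contributes one point per ROI.
#'
#' @param rois list of [roi_mask()] objects sharing one grid.
#' @param fraction subsample fraction in (0, 1].
#' @param seed integer seed for the subsample draw.
#' @return An object of class `calc_points`: list with `points` (n x 3 matrix,
#'   cm), `voxel_volume` (grid voxel volume, cm^3), `roi_membership` (named
#'   list of index vectors into `points`), `roi_roles` (named character) and
#'   `roi_point_volume` (named numeric: the volume each sampled point
#'   represents per ROI — `voxel_volume / fraction` up to rounding — so that
#'   absolute-volume DVH metrics refer to the full ROI volume).
#' @export
sample_calc_points <- function(rois, fraction = 1, seed = 1L) {
  if (!is.list(rois) || length(rois) == 0L) abort_input("`rois` must be non-empty")
  if (!is_number(fraction) || fraction <= 0 || fraction > 1)
    abort_input("`fraction` must be in (0, 1]")
  g0 <- rois[[1]]$grid
  for (r in rois) if (!same_grid(r$grid, g0))
    abort_input("all ROIs must share a single grid")

  picks <- with_private_seed(seed, lapply(rois, function(roi) {
    centers <- voxel_centers(roi)
    n <- nrow(centers)
    if (fraction < 1) {
      k <- max(1L, round(fraction * n))
      centers <- centers[sort(sample.int(n, k)), , drop = FALSE]
    }
    centers
  }))

  occupied <- vapply(rois, function(roi) sum(roi$occupancy), 0L)
  counts <- vapply(picks, nrow, 0L)
  points <- do.call(rbind, picks)
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  membership <- Map(seq.int, starts, ends)
  names(membership) <- vapply(rois, `[[`, "", "name")
  roles <- vapply(rois, `[[`, "", "role")
  names(roles) <- names(membership)

  vox <- prod(g0$spacing)
  point_volume <- vox * occupied / counts
  names(point_volume) <- names(membership)

  structure(list(points = points,
                 voxel_volume = vox,
                 roi_membership = membership,
                 roi_roles = roles,
                 roi_point_volume = point_volume),
            class = "calc_points")
}

#' Read/write a phantom description (grid, ROI masks, channels) as JSON
#'
#' The on-disk format is versioned structured text: the grid spec, per-ROI
#' run-length-encoded occupancy (over the column-major linearized volume),
#' and each channel as a coordinate list.
#'
#' @param phantom list with elements `channels` (list of [channel()]) and
#'   `rois` (list of [roi_mask()]).
#' @param path file path.
#' @return for `read_phantom_json`, a phantom list; for `write_phantom_json`,
#'   `path` invisibly.
#' @export
write_phantom_json <- function(phantom, path) {
  grid <- phantom$rois[[1]]$grid
  rois <- lapply(phantom$rois, function(roi) {
    rl <- rle(as.vector(roi$occupancy))
    list(name = roi$name, role = roi$role,
         rle_lengths = rl$lengths, rle_values = as.integer(rl$values))
  })
  chans <- lapply(phantom$channels, function(ch)
    list(name = ch$name, step = ch$step,
         dwell_positions = unname(ch$dwell_positions)))
  obj <- list(format = "hdrplan-phantom", version = 1L,
              grid = list(origin = grid$origin, spacing = grid$spacing,
                          dims = grid$dims),
              rois = rois, channels = chans)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("phantom file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "hdrplan-phantom"))
    abort_config("not an hdrplan phantom file")
  grid <- list(origin = as.numeric(unlist(obj$grid$origin)),
               spacing = as.numeric(unlist(obj$grid$spacing)),
               dims = as.integer(unlist(obj$grid$dims)))
  rois <- lapply(obj$rois, function(r) {
    occ <- inverse.rle(structure(list(
      lengths = as.integer(unlist(r$rle_lengths)),
      values = as.logical(unlist(r$rle_values))), class = "rle"))
    roi_mask(r$name, r$role, grid, array(occ, dim = grid$dims))
  })
  names(rois) <- vapply(rois, `[[`, "", "name")
  chans <- lapply(obj$channels, function(ch) {
    pos <- do.call(rbind, lapply(ch$dwell_positions, function(p) as.numeric(unlist(p))))
    channel(ch$name, pos, step = as.numeric(ch$step))
  })
  list(channels = chans, rois = rois)
}

#' Read/write a dwell-time plan CSV
#'
#' Columns: `channel,dwell_index,x_cm,y_cm,z_cm,time_s`. This CSV is the
#' single interchange format between optimization and reporting.
#'
#' @param plan a [plan()] with dwell times set.
#' @param path file path.
#' @export
write_plan_csv <- function(plan, path) {
  rows <- do.call(rbind, lapply(seq_along(plan$channels), function(m) {
    ch <- plan$channels[[m]]
    data.frame(channel = ch$name,
               dwell_index = seq_len(nrow(ch$dwell_positions)),
               x_cm = ch$dwell_positions[, 1],
               y_cm = ch$dwell_positions[, 2],
               z_cm = ch$dwell_positions[, 3],
               time_s = plan$dwell_times[[m]])
  }))
  # fixed full-precision formatting so identical plans produce identical bytes
  for (col in c("x_cm", "y_cm", "z_cm", "time_s"))
    rows[[col]] <- sprintf("%.17g", rows[[col]])
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plan_csv
#' @return for `read_plan_csv`, a [plan()].
#' @export
read_plan_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("plan CSV not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "dwell_index", "x_cm", "y_cm", "z_cm", "time_s")
  if (!all(need %in% names(df))) abort_input("plan CSV missing required columns")
  chans <- list(); times <- list()
  for (nm in unique(df$channel)) {
    sub <- df[df$channel == nm, ]
    sub <- sub[order(sub$dwell_index), ]
    chans[[length(chans) + 1L]] <-
      channel(nm, cbind(sub$x_cm, sub$y_cm, sub$z_cm))
    times[[length(times) + 1L]] <- sub$time_s
  }
  plan(chans, times)
}
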