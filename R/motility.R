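# Migration-track speed analysis: per-cell mean speed from frame-indexed
# coordinates, and per-condition aggregation.

#' Single-cell migration track
#'
#' @param cell_id identifier.
#' @param frames strictly increasing integer frame indices.
#' @param positions n x 2 matrix of (x, y) positions, in pixels (or in
#'   micrometres with `pixel_size = 1`).
#' @param frame_interval minutes between consecutive frames (default 10).
#' @param pixel_size micrometres per pixel (default 1, i.e. positions
#'   already in micrometres).
#' @return An object of class `track`.
#' @export
track <- function(cell_id, frames, positions, frame_interval = 10,
                  pixel_size = 1) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  frames <- as.integer(frames)
  if (nrow(positions) < 2L) {
    stop("a track needs at least 2 positions", call. = FALSE)
  }
  if (length(frames) != nrow(positions)) {
    stop("`frames` and `positions` lengths differ", call. = FALSE)
  }
  if (any(diff(frames) <= 0L)) {
    stop("`frames` must be strictly increasing", call. = FALSE)
  }
  structure(list(cell_id = as.character(cell_id), frames = frames,
                 positions = positions, frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> %s: %d positions, %g min/frame\n", x$cell_id,
              nrow(x$positions), x$frame_interval))
  invisible(x)
}

#' Mean speed of a migration track
#'
#' Step displacements are Euclidean distances between consecutive
#' positions scaled by `pixel_size`; mean speed is total path length over
#' total elapsed time.  Missing frames (gaps in the frame index) are
#' bridged by a single straight step whose duration is the gap times the
#' frame interval — matching how trackers export dropped frames — and the
#' track is flagged `has_gaps`.  Speed is invariant to global translation
#' and rotation of the coordinates.
#'
#' @param trk a [track()] object.
#' @return list with `cell_id`, `mean_speed` (um/min), `path_length`
#'   (um), `n_steps`, `elapsed_min`, `has_gaps`.
#' @examples
#' trk <- track("c1", 0:10, cbind(seq(0, 50, 5), 0), frame_interval = 10)
#' track_speed(trk)$mean_speed  # 0.5 um/min
#' @export
track_speed <- function(trk) {
  stopifnot(inherits(trk, "track"))
  d_px <- sqrt(rowSums(diff(trk$positions)^2))
  d_um <- d_px * trk$pixel_size
  gap <- diff(trk$frames)
  elapsed <- sum(gap) * trk$frame_interval
  list(cell_id = trk$cell_id,
       mean_speed = sum(d_um) / elapsed,
       path_length = sum(d_um),
       n_steps = length(d_um),
       elapsed_min = elapsed,
       has_gaps = any(gap > 1L))
}

#' Per-condition migration speed summary
#'
#' Aggregates per-cell mean speeds by condition.  Cells, not steps, are
#' the experimental unit: the condition mean is the mean of per-cell
#' means and the SEM is taken over cells.
#'
#' @param tracks list of [track()] objects.
#' @param labels character vector, one condition label per track.
#' @param conditions optional vector of expected condition labels; a
#'   label outside this set is an error.
#' @return data.frame with columns condition, n_cells, mean_speed,
#'   sem_speed.
#' @export
condition_summary <- function(tracks, labels, conditions = unique(labels)) {
  if (length(tracks) == 0L) stop("no tracks supplied", call. = FALSE)
  if (length(labels) != length(tracks)) {
    stop("every track must carry a condition label", call. = FALSE)
  }
  if (any(!labels %in% conditions)) {
    stop(sprintf("unknown condition label: %s",
                 paste(setdiff(labels, conditions), collapse = ", ")),
         call. = FALSE)
  }
  speeds <- vapply(tracks, function(t) track_speed(t)$mean_speed, numeric(1))
  rows <- lapply(conditions, function(cond) {
    s <- speeds[labels == cond]
    if (length(s) == 0L) {
      stop(sprintf("condition '%s' has no tracks", cond), call. = FALSE)
    }
    data.frame(condition = cond, n_cells = length(s), mean_speed = mean(s),
               sem_speed = if (length(s) > 1) stats::sd(s) / sqrt(length(s)) else 0)
  })
  do.call(rbind, rows)
}
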