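#' Per-point motion-class codes
#'
#' The package-wide integer encoding of the two motion classes:
#' `moving` (directed transport) is `1L`, `not_moving` (stalled, Brownian or
#' confined motion) is `0L`. The encoding is stable across save/load.
#'
#' @return Named integer vector `c(not_moving = 0L, moving = 1L)`.
#' @export
label_codes <- function() {
  c(not_moving = 0L, moving = 1L)
}

#' Construct a particle trajectory
#'
#' A trajectory is an ordered sequence of 2D positions of one tracked
#' particle, one position per frame, with optional per-point binary motion
#' labels. It is the unit of I/O, segmentation and evaluation.
#'
#' @param track_id Character scalar identifying the track.
#' @param frames Integer vector of frame indices, strictly increasing.
#' @param coords Numeric matrix with one row per point and two columns
#'   (x, y). Units (pixels or micrometres) are carried as metadata and never
#'   converted: all downstream features are displacement-based and
#'   scale-covariant.
#' @param labels Optional integer vector of per-point class codes
#'   (see [label_codes()]), one per point.
#' @param unit Optional unit string (e.g. `"pixel"`), metadata only.
#' @return An object of class `trajectory`: a list with fields `track_id`,
#'   `frames`, `coords`, `labels`, `unit`.
#' @examples
#' tr <- trajectory("t1", 0:4, cbind(0:4, 0), labels = c(1, 1, 1, 0, 0))
#' trajectory_length(tr)
#' @export
trajectory <- function(track_id, frames, coords, labels = NULL, unit = NA_character_) {
  track_id <- as.character(track_id)
  stopifnot(length(track_id) == 1L)
  frames <- as.integer(frames)
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 2L)
    stop("coords must be an L x 2 matrix of (x, y) positions")
  storage.mode(coords) <- "double"
  L <- nrow(coords)
  if (L < 1L) stop("a trajectory must contain at least one point")
  if (length(frames) != L)
    stop(sprintf("track '%s': %d frames but %d coordinate rows", track_id, length(frames), L))
  if (L > 1L && any(diff(frames) <= 0L))
    stop(sprintf("track '%s': frame indices must be strictly increasing", track_id))
  if (!all(is.finite(coords)))
    stop(sprintf("track '%s': coordinates contain non-finite values", track_id))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != L)
      stop(sprintf("track '%s': %d labels for %d points", track_id, length(labels), L))
    if (any(is.na(labels)) || !all(labels %in% label_codes()))
      stop(sprintf("track '%s': labels must all be 0 (not_moving) or 1 (moving)", track_id))
  }
  if (L > 1L && any(diff(frames) > 1L))
    warning(sprintf("track '%s' has frame gaps; points are treated as consecutive", track_id))
  structure(
    list(track_id = track_id, frames = frames, coords = coords,
         labels = labels, unit = unit),
    class = "trajectory"
  )
}

#' Number of points in a trajectory
#' @param traj A [trajectory()].
#' @return Integer point count.
#' @export
trajectory_length <- function(traj) nrow(traj$coords)

#' @export
print.trajectory <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unlabelled"
         else sprintf("%d/%d points moving", sum(x$labels), length(x$labels))
  cat(sprintf("<trajectory '%s': %d points, frames %d..%d, %s>\n",
              x$track_id, trajectory_length(x),
              x$frames[1L], x$frames[length(x$frames)], lab))
  invisible(x)
}

# Assert that every trajectory in a list is labelled; used by training.
assert_labelled <- function(trajs) {
  for (tr in trajs) {
    if (is.null(tr$labels))
      stop(sprintf("track '%s' has no labels; training requires fully labelled trajectories",
                   tr$track_id))
  }
  invisible(TRUE)
}
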