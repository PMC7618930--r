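#' Sliding-window specification
#'
#' Parameters of the sliding window moved along each trajectory. The defaults
#' follow the segmentation protocol: a window of `W = 8` points, a stride of
#' 25% of the window length (`step = round(0.25 * W)`, at least 1), and a
#' centre fraction of 50%, i.e. only the central half of each interior window
#' contributes to the stitched result, while the first window additionally
#' contributes its leading quarter and the last its trailing quarter.
#'
#' @param W Window length in points. Must be at least 4 and divisible by
#'   `2^depth` of the network (4 for the default two-level U-Net) so the
#'   bottleneck length is a whole number.
#' @param step Stride between window starts; default `round(0.25 * W)`.
#' @param center_fraction Fraction of each window contributing to stitching.
#' @return Object of class `window_spec` with fields `W`, `step`,
#'   `center_fraction`, `center_len`, `center_off` (0-based offset of the
#'   centre block within a window).
#' @examples
#' window_spec()          # W = 8, step = 2, centre = positions 2..5
#' window_spec(W = 16)    # step = 4, centre = positions 4..11
#' @export
window_spec <- function(W = 8L, step = max(1L, as.integer(round(0.25 * W))),
                        center_fraction = 0.5) {
  W <- as.integer(W); step <- as.integer(step)
  if (W < 4L) stop("window length W must be >= 4")
  if (W %% 4L != 0L)
    stop("W must be divisible by 4 (2^depth of the two-level U-Net)")
  if (step < 1L || step > W) stop("step must satisfy 1 <= step <= W")
  if (!(center_fraction > 0 && center_fraction <= 1))
    stop("center_fraction must be in (0, 1]")
  center_len <- as.integer(round(center_fraction * W))
  if (center_len < step)
    stop(sprintf("centre length %d < step %d: stitching would leave gaps",
                 center_len, step))
  structure(
    list(W = W, step = step, center_fraction = center_fraction,
         center_len = center_len,
         center_off = as.integer(floor((W - center_len) / 2))),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec: W=%d, step=%d, centre %d..%d (fraction %.2f)>\n",
              x$W, x$step, x$center_off, x$center_off + x$center_len - 1L,
              x$center_fraction))
  invisible(x)
}

#' Pad a short trajectory to the window length
#'
#' Trajectories shorter than the window length `W` are padded by repeating
#' their last observed point, so the appended tail has zero displacement —
#' stalled behaviour — and is labelled `not_moving`. Padded positions are
#' marked invalid in the returned mask and are stripped again after
#' stitching.
#'
#' @param traj A [trajectory()].
#' @param W Target minimum length (window length).
#' @return List with `coords` (max(L, W) x 2), `valid_mask` (logical, FALSE on
#'   padded positions), `labels` (padded with `not_moving`, or NULL if the
#'   input is unlabelled), and `n_original`.
#' @export
pad_trajectory <- function(traj, W) {
  W <- as.integer(W)
  if (W < 1L) stop("W must be >= 1")
  L <- trajectory_length(traj)
  if (L >= W) {
    return(list(coords = traj$coords, valid_mask = rep(TRUE, L),
                labels = traj$labels, n_original = L))
  }
  n_pad <- W - L
  last <- traj$coords[L, , drop = FALSE]
  coords <- rbind(traj$coords, last[rep(1L, n_pad), , drop = FALSE])
  labels <- if (is.null(traj$labels)) NULL else c(traj$labels, rep(0L, n_pad))
  list(coords = coords,
       valid_mask = c(rep(TRUE, L), rep(FALSE, n_pad)),
       labels = labels, n_original = L)
}

#' Enumerate sliding windows over a padded trajectory
#'
#' Window starts are `0, step, 2*step, ...` (0-based offsets into the padded
#' trajectory); the final start is snapped to `L - W` so the tail is always
#' covered. Each window carries a `weight_mask` marking the positions it
#' contributes to stitching: interior windows contribute their centre block
#' only, the first window additionally its leading edge and the last its
#' trailing edge. Every padded index is covered by at least one mask.
#'
#' @param L Padded trajectory length (must be >= `spec$W`).
#' @param spec A [window_spec()].
#' @return List of `list(start, weight_mask)`, one per window; `start` is the
#'   0-based offset, `weight_mask` a logical vector of length `W`.
#' @export
enumerate_windows <- function(L, spec) {
  L <- as.integer(L)
  W <- spec$W
  if (L < W)
    stop(sprintf("padded length %d < window length %d: pad the trajectory first", L, W))
  starts <- seq.int(0L, L - W, by = spec$step)
  if (starts[length(starts)] != L - W) starts <- c(starts, L - W)
  n <- length(starts)
  lapply(seq_len(n), function(i) {
    mask <- rep(FALSE, W)
    mask[(spec$center_off + 1L):(spec$center_off + spec$center_len)] <- TRUE
    if (i == 1L && spec$center_off > 0L) mask[1:spec$center_off] <- TRUE
    if (i == n) {
      tail_start <- spec$center_off + spec$center_len + 1L
      if (tail_start <= W) mask[tail_start:W] <- TRUE
    }
    list(start = starts[i], weight_mask = mask)
  })
}

#' Origin-normalize a window of positions
#'
#' Subtracts the window's own first position from every position, translating
#' each window to a common origin while preserving its displacements. The
#' normalization is per-window, not per-trajectory, and is exactly
#' translation-invariant.
#'
#' @param coords W x 2 matrix of positions.
#' @return W x 2 matrix of displacements; row 1 is (0, 0).
#' @export
normalize_window <- function(coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("window coordinates must be finite")
  sweep(coords, 2L, coords[1L, ], "-")
}

#' Convert origin-normalized displacements to polar coordinates
#'
#' Maps each displacement `(x, y)` to `(r, theta)` with `r = sqrt(x^2 + y^2)`
#' and `theta = atan2(y, x)` wrapped to `(-pi, pi]`; `theta` at the origin is
#' defined as 0. `r` collapses displacement magnitude into a single channel
#' regardless of direction, which is the motivation for the polar
#' representation.
#'
#' @param displacements W x 2 matrix with first row (0, 0).
#' @return W x 2 matrix with columns `r`, `theta`.
#' @export
to_polar <- function(displacements) {
  x <- displacements[, 1L]; y <- displacements[, 2L]
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)          # 0 at the origin by atan2(0, 0) = 0
  theta[theta <= -pi] <- pi     # wrap -pi to pi so the range is (-pi, pi]
  cbind(r = r, theta = theta)
}

#' Build model-ready windows for one trajectory
#'
#' Composes the preprocessing pipeline: pad to the window length, enumerate
#' sliding windows, origin-normalize each window to its own first point, and
#' optionally convert to polar coordinates. Feature matrices are channels x W
#' (channel 1 = x or r, channel 2 = y or theta).
#'
#' @param traj A [trajectory()].
#' @param spec A [window_spec()].
#' @param coord_system `"cartesian"` or `"polar"`.
#' @return List of windows: `list(start, features, valid_mask, labels,
#'   weight_mask)`; `labels` is NULL for unlabelled input. The padded length
#'   is attached as attribute `padded_length`, the original length as
#'   `n_original`.
#' @export
build_features <- function(traj, spec = window_spec(),
                           coord_system = c("polar", "cartesian")) {
  coord_system <- match.arg(coord_system)
  padded <- pad_trajectory(traj, spec$W)
  L <- nrow(padded$coords)
  wins <- enumerate_windows(L, spec)
  out <- lapply(wins, function(w) {
    idx <- (w$start + 1L):(w$start + spec$W)
    disp <- normalize_window(padded$coords[idx, , drop = FALSE])
    feat <- if (coord_system == "polar") to_polar(disp) else disp
    list(start = w$start,
         features = t(feat),  # channels x W
         valid_mask = padded$valid_mask[idx],
         labels = if (is.null(padded$labels)) NULL else padded$labels[idx],
         weight_mask = w$weight_mask)
  })
  attr(out, "padded_length") <- L
  attr(out, "n_original") <- padded$n_original
  out
}
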