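#' Segment one trajectory with a trained model
#'
#' Rebuilds features exactly as at training time (same window specification
#' and coordinate system, both read from the artifact), runs the network on
#' every window, and stitches the per-window probabilities back onto the
#' points: each point's final probability is the unweighted mean over all
#' windows whose weight mask covers it (interior windows contribute their
#' centre half; the first and last windows also contribute their outer
#' edges). Padded positions are dropped, so the result has the original
#' trajectory length. The hard label is `moving` iff the stitched
#' probability exceeds 0.5 (a tie at exactly 0.5 is `not_moving`).
#'
#' @param artifact A `trajseg_model` from [train_unet()] or [load_model()].
#' @param traj A [trajectory()].
#' @return Object of class `segmentation`: list with `track_id`, `frames`,
#'   `probability` (length L), `label` (0/1, length L), and
#'   `n_contributing` (windows covering each point, all >= 1).
#' @export
segment_trajectory <- function(artifact, traj) {
  spec <- artifact$window_spec
  if (is.null(spec)) spec <- window_spec()
  cs <- artifact$coord_system
  if (is.null(cs)) cs <- "polar"
  wins <- build_features(traj, spec, cs)
  L_pad <- attr(wins, "padded_length")
  L <- attr(wins, "n_original")
  n <- length(wins); W <- spec$W
  X <- array(0, dim = c(n, artifact$model$config$in_channels, W))
  for (i in seq_len(n)) X[i, , ] <- wins[[i]]$features
  prob <- unet_forward(artifact$model, X)$prob

  acc <- numeric(L_pad)
  cnt <- integer(L_pad)
  for (i in seq_len(n)) {
    w <- wins[[i]]
    pos <- which(w$weight_mask)
    gidx <- w$start + pos
    acc[gidx] <- acc[gidx] + prob[i, pos]
    cnt[gidx] <- cnt[gidx] + 1L
  }
  stopifnot(all(cnt >= 1L))
  p <- (acc / cnt)[seq_len(L)]
  structure(
    list(track_id = traj$track_id, frames = traj$frames,
         probability = p, label = as.integer(p > 0.5),
         n_contributing = cnt[seq_len(L)]),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation '%s': %d points, %d moving>\n",
              x$track_id, length(x$label), sum(x$label)))
  invisible(x)
}

#' Segment a list of trajectories
#'
#' @param artifact A `trajseg_model`.
#' @param trajs List of [trajectory()] objects.
#' @return List of [segment_trajectory()] results, one per trajectory.
#' @export
segment_all <- function(artifact, trajs) {
  lapply(trajs, function(tr) segment_trajectory(artifact, tr))
}

#' Write segmentation results as a labelled CSV
#'
#' Emits the original columns (track id, frame, x, y, and the reference
#' label when present) plus `probability` and `predicted_label`. The file
#' can be re-read with [read_trajectories()] using a `column_map` with
#' `label = "predicted_label"`.
#'
#' @param results List of `segmentation` objects.
#' @param trajs The matching input trajectories (same order).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(results, trajs, path) {
  if (length(results) != length(trajs))
    stop("results and trajs must have the same length")
  any_ref <- any(vapply(trajs, function(t) !is.null(t$labels), logical(1L)))
  header <- c("track_id", "frame", "x", "y", if (any_ref) "label",
              "probability", "predicted_label")
  lines <- paste(header, collapse = ",")
  for (i in seq_along(results)) {
    res <- results[[i]]; tr <- trajs[[i]]
    if (res$track_id != tr$track_id)
      stop(sprintf("result/trajectory mismatch at position %d: '%s' vs '%s'",
                   i, res$track_id, tr$track_id))
    L <- trajectory_length(tr)
    row <- paste(rep(tr$track_id, L), tr$frames,
                 sprintf("%.17g", tr$coords[, 1L]),
                 sprintf("%.17g", tr$coords[, 2L]), sep = ",")
    if (any_ref) {
      lab <- if (is.null(tr$labels)) rep("", L) else as.character(tr$labels)
      row <- paste(row, lab, sep = ",")
    }
    row <- paste(row, sprintf("%.17g", res$probability), res$label, sep = ",")
    lines <- c(lines, row)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
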