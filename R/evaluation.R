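#' Score segmentations against reference labels
#'
#' Computes point accuracy with the first point of each trajectory excluded
#' (a single starting position carries no dynamics, so it is never scored).
#' Accuracy is micro-averaged over all scored points:
#' `correct / sum(L_i - 1)`. Per-class precision and recall and the full
#' confusion table are reported alongside, because realistic datasets are
#' class-imbalanced and a single accuracy can hide a degenerate classifier.
#'
#' @param preds List of `segmentation` results ([segment_trajectory()]).
#' @param refs List of labelled reference [trajectory()] objects with
#'   matching track ids and lengths (any order).
#' @return Object of class `eval_report`: `accuracy`, `precision` and
#'   `recall` (named by class), `confusion` (2 x 2 table, reference in
#'   rows), `n_scored`, and `per_track` (data.frame of per-trajectory
#'   accuracies).
#' @export
point_accuracy <- function(preds, refs) {
  ref_ids <- vapply(refs, `[[`, character(1L), "track_id")
  conf <- matrix(0L, 2L, 2L,
                 dimnames = list(ref = c("not_moving", "moving"),
                                 pred = c("not_moving", "moving")))
  per_track <- data.frame(track_id = character(0), n_scored = integer(0),
                          accuracy = numeric(0))
  for (pr in preds) {
    j <- match(pr$track_id, ref_ids)
    if (is.na(j))
      stop(sprintf("no reference trajectory for track '%s'", pr$track_id))
    ref <- refs[[j]]
    if (is.null(ref$labels))
      stop(sprintf("reference track '%s' is unlabelled", ref$track_id))
    L <- trajectory_length(ref)
    if (length(pr$label) != L)
      stop(sprintf("track '%s': prediction length %d != reference length %d",
                   pr$track_id, length(pr$label), L))
    if (L < 2L) {
      per_track <- rbind(per_track, data.frame(
        track_id = pr$track_id, n_scored = 0L, accuracy = NA_real_))
      next
    }
    idx <- 2L:L  # first point excluded from evaluation
    y <- ref$labels[idx]; yhat <- pr$label[idx]
    for (a in 0:1) for (b in 0:1)
      conf[a + 1L, b + 1L] <- conf[a + 1L, b + 1L] + sum(y == a & yhat == b)
    per_track <- rbind(per_track, data.frame(
      track_id = pr$track_id, n_scored = L - 1L,
      accuracy = mean(y == yhat)))
  }
  n_scored <- sum(conf)
  accuracy <- if (n_scored > 0) sum(diag(conf)) / n_scored else NA_real_
  precision <- diag(conf) / pmax(colSums(conf), 1L)
  recall <- diag(conf) / pmax(rowSums(conf), 1L)
  names(precision) <- names(recall) <- rownames(conf)
  structure(
    list(accuracy = accuracy, precision = precision, recall = recall,
         confusion = conf, n_scored = n_scored, per_track = per_track),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("point accuracy: %.4f  (%d scored points, first point of each track excluded)\n",
              x$accuracy, x$n_scored))
  cat(sprintf("  moving:     precision %.3f  recall %.3f\n",
              x$precision["moving"], x$recall["moving"]))
  cat(sprintf("  not_moving: precision %.3f  recall %.3f\n",
              x$precision["not_moving"], x$recall["not_moving"]))
  invisible(x)
}

#' Coordinate-system comparison experiment
#'
#' Trains two models that are identical (architecture, window
#' specification, seed, optimization) except for the coordinate system of
#' the input features — Cartesian displacements versus polar (r, theta) —
#' then evaluates both on the same held-out trajectories and reports the
#' two accuracies side by side. No ordering between the two is asserted:
#' which representation wins is dataset-dependent and the margin is
#' typically small.
#'
#' @param train_trajs,test_trajs Labelled trajectory lists.
#' @param base_config A [train_config()]; its `coord_system` is overridden
#'   for each arm.
#' @param spec A [window_spec()].
#' @param verbose Print per-arm progress.
#' @return List with `table` (data.frame: coord_system, accuracy, n_scored),
#'   `reports` (the two `eval_report`s) and `models` (the two artifacts).
#' @export
coordinate_comparison <- function(train_trajs, test_trajs,
                                  base_config = train_config(),
                                  spec = window_spec(), verbose = FALSE) {
  arms <- c("cartesian", "polar")
  reports <- list(); models <- list()
  for (cs in arms) {
    cfg <- base_config
    cfg$coord_system <- cs
    ts <- build_training_set(train_trajs, spec, cs)
    if (verbose)
      message(sprintf("[%s] %d trajectories -> %d windows", cs,
                      length(train_trajs), dim(ts$features)[1L]))
    net <- build_unet(unet_config(seed = cfg$seed))
    art <- train_unet(net, ts, cfg, spec, verbose = verbose)
    preds <- segment_all(art, test_trajs)
    reports[[cs]] <- point_accuracy(preds, test_trajs)
    models[[cs]] <- art
    if (verbose)
      message(sprintf("[%s] test accuracy %.4f", cs, reports[[cs]]$accuracy))
  }
  tab <- data.frame(
    coord_system = arms,
    accuracy = vapply(reports, `[[`, numeric(1L), "accuracy"),
    n_scored = vapply(reports, `[[`, numeric(1L), "n_scored"),
    row.names = NULL
  )
  list(table = tab, reports = reports, models = models)
}
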