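# Shared fixtures: random valid trajectories and independent brute-force
# oracles for windowing and stitching. The oracles are deliberately written
# as plain loops over explicit (point, window) pairs, independent of the
# vectorized implementation they check.

random_trajectory <- function(id = "t1", L = 10L, labelled = FALSE) {
  trajectory(
    track_id = id,
    frames = cumsum(c(0L, rep(1L, L - 1L))),
    coords = cbind(cumsum(stats::rnorm(L)), cumsum(stats::rnorm(L))),
    labels = if (labelled) sample(0:1, L, replace = TRUE) else NULL
  )
}

# Brute-force enumeration of window starts and of the (point, window)
# contribution pairs, following the stitching rule from first principles:
# march in strides of `step`, snap the final start to L - W; interior
# windows contribute their centre block, the first window also its leading
# edge, the last also its trailing edge.
oracle_window_pairs <- function(L, W = 8L, step = 2L, center_frac = 0.5) {
  starts <- integer(0)
  s <- 0L
  while (s < L - W) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts <- c(starts, L - W)
  center_len <- as.integer(round(center_frac * W))
  off <- as.integer(floor((W - center_len) / 2))
  pairs <- list()
  for (i in seq_along(starts)) {
    local_idx <- off:(off + center_len - 1L)           # 0-based within window
    if (i == 1L && off > 0L) local_idx <- c(0:(off - 1L), local_idx)
    if (i == length(starts) && off + center_len < W)
      local_idx <- c(local_idx, (off + center_len):(W - 1L))
    for (li in local_idx)
      pairs[[length(pairs) + 1L]] <- c(point = starts[i] + li, window = i)
  }
  list(starts = starts, pairs = do.call(rbind, pairs))
}

# Explicit contribution-list stitching: run the model one window at a time
# and average the probabilities listed for each point.
oracle_stitch <- function(artifact, traj) {
  spec <- artifact$window_spec
  padded <- pad_trajectory(traj, spec$W)
  L_pad <- nrow(padded$coords)
  oc <- oracle_window_pairs(L_pad, spec$W, spec$step, spec$center_fraction)
  wins <- build_features(traj, spec, artifact$coord_system)
  contrib <- vector("list", L_pad)
  for (k in seq_len(nrow(oc$pairs))) {
    pt <- oc$pairs[k, "point"]; wi <- oc$pairs[k, "window"]
    w <- wins[[wi]]
    X <- array(w$features, dim = c(1L, nrow(w$features), spec$W))
    p <- unet_forward(artifact$model, X)$prob
    local_pos <- pt - w$start + 1L
    contrib[[pt + 1L]] <- c(contrib[[pt + 1L]], p[1L, local_pos])
  }
  vapply(contrib, mean, numeric(1L))[seq_len(trajectory_length(traj))]
}

# An untrained artifact with default preprocessing metadata, for tests that
# need a deterministic model but no training.
untrained_artifact <- function(seed = 0L, coord_system = "polar",
                               spec = window_spec()) {
  structure(
    list(model = build_unet(unet_config(seed = seed)),
         coord_system = coord_system, window_spec = spec,
         train_config = NULL, history = NULL),
    class = "trajseg_model"
  )
}
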