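#' Training configuration
#'
#' The optimizer and loss follow the segmentation protocol: Adam with
#' learning rate 1e-4 minimizing binary cross-entropy averaged per point.
#' Epochs, batch size and shuffling are package choices sized for
#' CPU-minutes training and fully exposed here. Padded points are included
#' in the loss as `not_moving` by default (padding is a zero-displacement
#' tail, i.e. stalled behaviour); set `include_padded_points_in_loss = FALSE`
#' to mask them out for ablation.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Number of passes over the training windows (default 200).
#' @param batch_size Windows per optimization step (default 32).
#' @param coord_system `"polar"` (default) or `"cartesian"`.
#' @param seed Integer seed governing weight init and batch shuffling.
#' @param include_padded_points_in_loss Count padded positions in the loss.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 200L, batch_size = 32L,
                         coord_system = c("polar", "cartesian"), seed = 0L,
                         include_padded_points_in_loss = TRUE) {
  coord_system <- match.arg(coord_system)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(
    list(learning_rate = learning_rate, epochs = epochs,
         batch_size = as.integer(batch_size), coord_system = coord_system,
         seed = as.integer(seed),
         include_padded_points_in_loss = isTRUE(include_padded_points_in_loss)),
    class = "train_config"
  )
}

#' Assemble a window training set from labelled trajectories
#'
#' Applies the full preprocessing pipeline to every trajectory and stacks
#' the resulting windows: one training sample per enumerated window. Padded
#' positions carry the `not_moving` label and `FALSE` in the validity mask.
#'
#' @param trajs List of fully labelled [trajectory()] objects.
#' @param spec A [window_spec()].
#' @param coord_system `"polar"` or `"cartesian"`.
#' @return List with `features` (n x 2 x W array), `labels` (n x W 0/1
#'   matrix), `valid` (n x W logical matrix, FALSE on padded positions) and
#'   `n_windows_per_track` (named integer vector).
#' @export
build_training_set <- function(trajs, spec = window_spec(),
                               coord_system = c("polar", "cartesian")) {
  coord_system <- match.arg(coord_system)
  assert_labelled(trajs)
  all_wins <- list()
  counts <- integer(length(trajs))
  for (i in seq_along(trajs)) {
    wins <- build_features(trajs[[i]], spec, coord_system)
    counts[i] <- length(wins)
    all_wins <- c(all_wins, wins)
  }
  names(counts) <- vapply(trajs, `[[`, character(1L), "track_id")
  n <- length(all_wins); W <- spec$W
  features <- array(0, dim = c(n, 2L, W))
  labels <- matrix(0L, n, W)
  valid <- matrix(TRUE, n, W)
  for (i in seq_len(n)) {
    features[i, , ] <- all_wins[[i]]$features
    labels[i, ] <- all_wins[[i]]$labels
    valid[i, ] <- all_wins[[i]]$valid_mask
  }
  list(features = features, labels = labels, valid = valid,
       n_windows_per_track = counts)
}

#' Binary cross-entropy loss over window points
#'
#' Mean over counted points of `-(y log p + (1 - y) log(1 - p))`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` so the result is always
#' finite. The mask selects which points are counted.
#'
#' @param pred n x W matrix of probabilities in (0, 1).
#' @param labels n x W matrix of 0/1 labels.
#' @param mask n x W logical matrix of counted points (default: all).
#' @return Scalar loss.
#' @export
bce_loss <- function(pred, labels, mask = NULL) {
  pred <- matrix(pred, nrow = NROW(pred))
  labels <- matrix(labels, nrow = NROW(labels))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pred), ncol(pred))
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  ll <- -(labels * log(p) + (1 - labels) * log(1 - p))
  sum(ll[mask]) / sum(mask)
}

#' Train the 1D U-Net on a window training set
#'
#' Mini-batch Adam on binary cross-entropy. All randomness (weight
#' initialization via the model's own seed, per-epoch shuffling via
#' `config$seed`) is seeded, so the loss history and final weights are
#' reproducible bit-for-bit on fixed data.
#'
#' @param model A [build_unet()] model (its weights are the starting point).
#' @param training_set As returned by [build_training_set()].
#' @param config A [train_config()].
#' @param spec The [window_spec()] used to build the training set (stored in
#'   the artifact so inference reproduces the same preprocessing).
#' @param verbose Print the loss every few epochs.
#' @return Object of class `trajseg_model`: list with `model`,
#'   `coord_system`, `window_spec`, `train_config`, and `history`
#'   (per-epoch mean loss).
#' @export
train_unet <- function(model, training_set, config = train_config(),
                       spec = window_spec(), verbose = FALSE) {
  X <- training_set$features
  Y <- training_set$labels
  mask <- if (config$include_padded_points_in_loss) {
    matrix(TRUE, nrow(Y), ncol(Y))
  } else {
    training_set$valid
  }
  n <- dim(X)[1L]
  if (n < 1L) stop("empty training set")

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  params <- model$params
  opt <- adam_init(params)
  history <- numeric(config$epochs)
  work_model <- model

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_pts <- 0
    for (b_start in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[b_start:min(b_start + config$batch_size - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      Mb <- mask[idx, , drop = FALSE]
      work_model$params <- params
      fw <- unet_forward(work_model, Xb, with_cache = TRUE)
      n_pts <- sum(Mb)
      loss_b <- bce_loss(fw$prob, Yb, Mb)
      if (!is.finite(loss_b))
        stop(sprintf("non-finite loss at epoch %d: check learning rate and input data", ep))
      # d(BCE)/d(logit) for sigmoid output: (p - y) / n_counted on counted points
      dLogit <- (fw$prob - Yb) * Mb / n_pts
      grads <- unet_backward(work_model, fw$cache, dLogit)
      upd <- adam_step(params, grads, opt, config$learning_rate)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss_b * n_pts
      ep_pts <- ep_pts + n_pts
    }
    history[ep] <- ep_loss / ep_pts
    if (verbose && (ep %% 20L == 0L || ep == 1L))
      message(sprintf("epoch %4d  loss %.5f", ep, history[ep]))
  }
  work_model$params <- params
  structure(
    list(model = work_model, coord_system = config$coord_system,
         window_spec = spec, train_config = config, history = history),
    class = "trajseg_model"
  )
}
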