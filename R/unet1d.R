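#' 1D U-Net architecture configuration
#'
#' Hyperparameters of the encoder-decoder. The architecture has two
#' down-sampling blocks (same-padded 1D convolution + ReLU, then max pooling
#' with stride 2), a bottleneck convolution, and two up-sampling blocks
#' (learned transposed convolution doubling the width, channel concatenation
#' with the matching encoder skip, convolution + ReLU). The head is a 1x1
#' convolution to a single channel followed by a sigmoid, read as the
#' per-point probability of the `moving` class; `P(not_moving) = 1 - P`.
#'
#' Channel widths double per level (`base_channels`, 2x, 4x at the
#' bottleneck). Input windows must have width divisible by `2^depth`.
#'
#' @param in_channels Feature channels per point (2: x,y or r,theta).
#' @param depth Number of down/up-sampling levels (fixed architecture: 2).
#' @param base_channels Channels of the first encoder block (default 16).
#' @param kernel_size Odd convolution kernel size (default 3).
#' @param seed Integer seed for deterministic weight initialization.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 2L, depth = 2L, base_channels = 16L,
                        kernel_size = 3L, seed = 0L) {
  if (depth != 2L) stop("this architecture is fixed at depth 2 (two down/up blocks)")
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd (same-padded convolutions)")
  structure(
    list(in_channels = as.integer(in_channels), depth = 2L,
         base_channels = as.integer(base_channels),
         kernel_size = as.integer(kernel_size), seed = as.integer(seed)),
    class = "unet_config"
  )
}

# Glorot-uniform init for a conv weight array (Cout, Cin, k).
glorot_conv <- function(Cout, Cin, k) {
  lim <- sqrt(6 / (Cin * k + Cout * k))
  array(stats::runif(Cout * Cin * k, -lim, lim), dim = c(Cout, Cin, k))
}

#' Build a 1D U-Net model
#'
#' Initializes all weights deterministically from `config$seed` (the global
#' RNG state is saved and restored). The returned object holds the
#' parameters and the configuration; it computes forward passes via
#' [unet_forward()].
#'
#' @param config A [unet_config()].
#' @return Object of class `unet1d`: list with `params` (named list of
#'   weight/bias arrays) and `config`.
#' @export
build_unet <- function(config = unet_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  cb <- config$base_channels; k <- config$kernel_size; cin <- config$in_channels
  c1 <- cb; c2 <- 2L * cb; c3 <- 4L * cb
  params <- list(
    enc1_W = glorot_conv(c1, cin, k), enc1_b = numeric(c1),
    enc2_W = glorot_conv(c2, c1, k),  enc2_b = numeric(c2),
    bott_W = glorot_conv(c3, c2, k),  bott_b = numeric(c3),
    up1_W  = glorot_conv(c2, c3, 2L), up1_b  = numeric(c2),
    dec1_W = glorot_conv(c2, 2L * c2, k), dec1_b = numeric(c2),
    up2_W  = glorot_conv(c1, c2, 2L), up2_b  = numeric(c1),
    dec2_W = glorot_conv(c1, 2L * c1, k), dec2_b = numeric(c1),
    head_W = glorot_conv(1L, c1, 1L), head_b = numeric(1L)
  )
  structure(list(params = params, config = config), class = "unet1d")
}

#' @export
print.unet1d <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("<unet1d: in=%d ch, levels %d/%d/%d, kernel %d, %d parameters>\n",
              x$config$in_channels, x$config$base_channels,
              2L * x$config$base_channels, 4L * x$config$base_channels,
              x$config$kernel_size, np))
  invisible(x)
}

check_batch <- function(model, X) {
  d <- dim(X)
  if (length(d) != 3L)
    stop(sprintf("batch must be a 3D array (n, channels, W); got %d dims", length(d)))
  if (d[2L] != model$config$in_channels)
    stop(sprintf("channel mismatch: model expects %d channels, batch has %d",
                 model$config$in_channels, d[2L]))
  if (d[3L] %% 2L^model$config$depth != 0L)
    stop(sprintf("window length %d not divisible by 2^depth = %d",
                 d[3L], 2L^model$config$depth))
  if (!all(is.finite(X))) stop("batch contains non-finite values")
  invisible(TRUE)
}

#' Forward pass of the 1D U-Net
#'
#' Maps a batch of feature windows to per-point probabilities of the
#' `moving` class.
#'
#' @param model A [build_unet()] model.
#' @param X Array of shape (n, in_channels, W) with W divisible by 4.
#' @param with_cache Keep intermediate activations for backpropagation.
#' @return List with `prob` (n x W matrix, values strictly in (0, 1)),
#'   `logit` (n x W pre-sigmoid), and `cache` when requested.
#' @export
unet_forward <- function(model, X, with_cache = FALSE) {
  check_batch(model, X)
  p <- model$params
  e1c <- conv1d_forward(X, p$enc1_W, p$enc1_b)
  e1r <- relu_forward(e1c$out)                 # skip 1, width W
  p1 <- maxpool2_forward(e1r$out)              # width W/2
  e2c <- conv1d_forward(p1$out, p$enc2_W, p$enc2_b)
  e2r <- relu_forward(e2c$out)                 # skip 2, width W/2
  p2 <- maxpool2_forward(e2r$out)              # width W/4
  bc <- conv1d_forward(p2$out, p$bott_W, p$bott_b)
  br <- relu_forward(bc$out)                   # bottleneck, width W/4
  u1 <- tconv2_forward(br$out, p$up1_W, p$up1_b)   # width W/2
  cat1 <- abind_channels(u1$out, e2r$out)
  d1c <- conv1d_forward(cat1, p$dec1_W, p$dec1_b)
  d1r <- relu_forward(d1c$out)
  u2 <- tconv2_forward(d1r$out, p$up2_W, p$up2_b)  # width W
  cat2 <- abind_channels(u2$out, e1r$out)
  d2c <- conv1d_forward(cat2, p$dec2_W, p$dec2_b)
  d2r <- relu_forward(d2c$out)
  hd <- conv1d_forward(d2r$out, p$head_W, p$head_b)
  logit <- hd$out[, 1L, , drop = TRUE]
  if (is.null(dim(logit))) logit <- matrix(logit, nrow = dim(X)[1L])
  prob <- 1 / (1 + exp(-logit))
  res <- list(prob = prob, logit = logit)
  if (with_cache) {
    res$cache <- list(e1c = e1c, e1r = e1r, p1 = p1, e2c = e2c, e2r = e2r,
                      p2 = p2, bc = bc, br = br, u1 = u1, d1c = d1c, d1r = d1r,
                      u2 = u2, d2c = d2c, d2r = d2r, hd = hd,
                      n_up1 = dim(u1$out)[2L], n_up2 = dim(u2$out)[2L])
  }
  res
}

# Concatenate two (n, C, W) arrays along the channel axis.
abind_channels <- function(A, B) {
  dA <- dim(A); dB <- dim(B)
  out <- array(0, dim = c(dA[1L], dA[2L] + dB[2L], dA[3L]))
  out[, seq_len(dA[2L]), ] <- A
  out[, dA[2L] + seq_len(dB[2L]), ] <- B
  out
}

# Backward pass: dLogit is the n x W gradient of the loss w.r.t. the
# pre-sigmoid output (for BCE + sigmoid this is simply (p - y) * weight).
# Returns a named list of gradients matching model$params.
unet_backward <- function(model, cache, dLogit) {
  n <- nrow(dLogit); W <- ncol(dLogit)
  dHead <- array(dLogit, dim = c(n, 1L, W))
  g <- list()
  b <- conv1d_backward(dHead, cache$hd$cache)
  g$head_W <- b$dW; g$head_b <- b$db
  dX <- relu_backward(b$dX, cache$d2r$cache)
  b <- conv1d_backward(dX, cache$d2c$cache)
  g$dec2_W <- b$dW; g$dec2_b <- b$db
  n_u2 <- cache$n_up2
  dU2 <- b$dX[, seq_len(n_u2), , drop = FALSE]
  dSkip1 <- b$dX[, n_u2 + seq_len(dim(b$dX)[2L] - n_u2), , drop = FALSE]
  b <- tconv2_backward(dU2, cache$u2$cache)
  g$up2_W <- b$dW; g$up2_b <- b$db
  dX <- relu_backward(b$dX, cache$d1r$cache)
  b <- conv1d_backward(dX, cache$d1c$cache)
  g$dec1_W <- b$dW; g$dec1_b <- b$db
  n_u1 <- cache$n_up1
  dU1 <- b$dX[, seq_len(n_u1), , drop = FALSE]
  dSkip2 <- b$dX[, n_u1 + seq_len(dim(b$dX)[2L] - n_u1), , drop = FALSE]
  b <- tconv2_backward(dU1, cache$u1$cache)
  g$up1_W <- b$dW; g$up1_b <- b$db
  dX <- relu_backward(b$dX, cache$br$cache)
  b <- conv1d_backward(dX, cache$bc$cache)
  g$bott_W <- b$dW; g$bott_b <- b$db
  dX <- maxpool2_backward(b$dX, cache$p2$cache)
  dX <- relu_backward(dX + dSkip2, cache$e2r$cache)
  b <- conv1d_backward(dX, cache$e2c$cache)
  g$enc2_W <- b$dW; g$enc2_b <- b$db
  dX <- maxpool2_backward(b$dX, cache$p1$cache)
  dX <- relu_backward(dX + dSkip1, cache$e1r$cache)
  b <- conv1d_backward(dX, cache$e1c$cache)
  g$enc1_W <- b$dW; g$enc1_b <- b$db
  g
}

#' Save or load a trained model artifact
#'
#' The checkpoint is a single self-describing file (serialized R object,
#' format version tagged) holding the architecture configuration, all
#' weights, and the training metadata (coordinate system, window
#' specification, loss history, seed) so that inference can reconstruct the
#' exact preprocessing used at training time. A load-after-save round trip
#' reproduces forward outputs bit-identically.
#'
#' @param artifact A model artifact as returned by [train_unet()] (or a bare
#'   [build_unet()] model, saved with empty metadata).
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the artifact.
#' @export
save_model <- function(artifact, path) {
  if (inherits(artifact, "unet1d")) {
    artifact <- list(model = artifact, coord_system = NULL,
                     window_spec = NULL, history = NULL, train_config = NULL)
    class(artifact) <- "trajseg_model"
  }
  if (!inherits(artifact, "trajseg_model"))
    stop("artifact must be a trajseg_model or unet1d object")
  payload <- unclass(artifact)
  payload$format_version <- 1L
  saveRDS(payload, path, version = 2L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$format_version))
    stop(sprintf("not a trajseg checkpoint: %s", path))
  if (payload$format_version != 1L)
    stop(sprintf("unsupported checkpoint format version %s", payload$format_version))
  if (is.null(payload$model) || !inherits(payload$model, "unet1d"))
    stop("corrupt checkpoint: missing model")
  payload$format_version <- NULL
  structure(payload, class = "trajseg_model")
}

#' @export
print.trajseg_model <- function(x, ...) {
  cs <- if (is.null(x$coord_system)) "untrained" else x$coord_system
  cat(sprintf("<trajseg_model: %s coordinates, W=%s>\n", cs,
              if (is.null(x$window_spec)) "?" else x$window_spec$W))
  print(x$model)
  invisible(x)
}
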