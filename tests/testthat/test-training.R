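test_that("binary cross-entropy matches closed forms and a manual oracle", {
  # uniform 0.5 predictions: loss is exactly ln 2 regardless of labels
  p <- matrix(0.5, 3L, 8L)
  y <- matrix(sample(0:1, 24, replace = TRUE), 3L, 8L)
  expect_equal(bce_loss(p, y), log(2), tolerance = 1e-12)

  # perfect prediction at the clamp boundary: loss ~ 0
  yy <- matrix(c(1, 0, 1, 1), 1L)
  pp <- matrix(c(1, 0, 1, 1), 1L)
  expect_lt(bce_loss(pp, yy), 1e-6)

  # 2-point hand-computed example: p = (0.8, 0.3), y = (1, 0)
  # loss = (-log 0.8 - log 0.7) / 2, computed independently term by term
  manual <- (-log(0.8) - log(0.7)) / 2
  expect_equal(bce_loss(matrix(c(0.8, 0.3), 1L), matrix(c(1, 0), 1L)),
               manual, tolerance = 1e-12)

  # masking: only counted points enter the mean
  p2 <- matrix(c(0.8, 0.5), 1L)
  y2 <- matrix(c(1, 1), 1L)
  expect_equal(bce_loss(p2, y2, matrix(c(TRUE, FALSE), 1L)),
               -log(0.8), tolerance = 1e-12)
  # extreme inputs stay finite thanks to clamping
  expect_true(is.finite(bce_loss(matrix(c(0, 1), 1L), matrix(c(1, 0), 1L))))
})

test_that("training-set assembly matches per-track window counts from the oracle", {
  set.seed(51)
  lens <- c(5L, 8L, 12L, 30L, 5L)
  trajs <- lapply(seq_along(lens), function(i)
    random_trajectory(sprintf("t%d", i), lens[i], labelled = TRUE))
  sp <- window_spec()
  ts <- build_training_set(trajs, sp, "polar")
  expected <- vapply(lens, function(L) {
    length(oracle_window_pairs(max(L, 8L))$starts)
  }, integer(1L))
  expect_equal(unname(ts$n_windows_per_track), expected)
  expect_equal(dim(ts$features), c(sum(expected), 2L, 8L))
  expect_equal(dim(ts$labels), c(sum(expected), 8L))
  # ten length-5 tracks pad to one window each
  short <- lapply(1:10, function(i)
    random_trajectory(sprintf("s%d", i), 5L, labelled = TRUE))
  expect_equal(dim(build_training_set(short, sp, "polar")$features)[1L], 10L)
})

test_that("training-set assembly refuses unlabelled trajectories by name", {
  trajs <- list(random_trajectory("lab", 8L, labelled = TRUE),
                random_trajectory("nolab", 8L, labelled = FALSE))
  expect_error(build_training_set(trajs, window_spec(), "polar"), "nolab")
})

test_that("train_config rejects invalid settings", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("training is deterministic under a fixed seed and the loss trends down", {
  set.seed(61)
  trajs <- lapply(1:6, function(i) random_trajectory(sprintf("t%d", i), 12L,
                                                     labelled = TRUE))
  sp <- window_spec()
  ts <- build_training_set(trajs, sp, "polar")
  cfg <- train_config(learning_rate = 0.005, epochs = 30L, seed = 9L)
  a <- train_unet(build_unet(unet_config(seed = 9L)), ts, cfg, sp)
  b <- train_unet(build_unet(unet_config(seed = 9L)), ts, cfg, sp)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  expect_lt(mean(tail(a$history, 5)), mean(head(a$history, 5)))
  # artifact carries the preprocessing metadata needed at inference time
  expect_identical(a$coord_system, "polar")
  expect_identical(a$window_spec$W, 8L)
})

test_that("padded points can be masked out of the loss for ablation", {
  tr <- random_trajectory("short", 5L, labelled = TRUE)
  ts <- build_training_set(list(tr), window_spec(), "polar")
  cfg_in <- train_config(epochs = 2L, seed = 1L,
                         include_padded_points_in_loss = TRUE)
  cfg_out <- train_config(epochs = 2L, seed = 1L,
                          include_padded_points_in_loss = FALSE)
  a <- train_unet(build_unet(unet_config(seed = 1L)), ts, cfg_in)
  b <- train_unet(build_unet(unet_config(seed = 1L)), ts, cfg_out)
  expect_false(identical(a$history, b$history))
})
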