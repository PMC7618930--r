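test_that("degenerate regimes produce their closed-form paths", {
  # stalled, no noise: all points identical, all labels not_moving
  cfg <- simulation_config(states = "stalled", sigma_loc = 0, seed = 1)
  set.seed(1)
  tr <- simulate_trajectory(cfg, length = 10L)
  expect_equal(nrow(unique(tr$coords)), 1L)
  expect_true(all(tr$labels == 0L))

  # directed, no jitter, no noise, v = 1, heading 0: unit steps along x
  cfg <- simulation_config(states = "directed", v = 1, sigma_phi = 0,
                           sigma_loc = 0, seed = 1)
  set.seed(1)
  tr <- simulate_trajectory(cfg, length = 5L, heading = 0)
  expect_equal(tr$coords[, 1L], c(0, 1, 2, 3, 4), ignore_attr = TRUE)
  expect_equal(tr$coords[, 2L], rep(0, 5), ignore_attr = TRUE)
  expect_true(all(tr$labels == 1L))
})

test_that("Brownian tracks reproduce the 2D diffusion law MSD = 2 sigma^2 tau", {
  cfg <- simulation_config(states = "brownian", sigma_b = 0.25, sigma_loc = 0,
                           seed = 7)
  set.seed(7)
  tr <- simulate_trajectory(cfg, length = 10000L)
  xy <- tr$coords
  taus <- 1:10
  msd <- vapply(taus, function(tau) {
    d <- xy[(1 + tau):nrow(xy), ] - xy[1:(nrow(xy) - tau), ]
    mean(rowSums(d^2))
  }, numeric(1L))
  slope <- sum(msd * taus) / sum(taus^2)  # least-squares through the origin
  expect_lt(abs(slope - 2 * 0.25^2) / (2 * 0.25^2), 0.15)
})

test_that("directed segments have mean step length near v", {
  cfg <- simulation_config(states = "directed", v = 1, sigma_phi = 0.2,
                           sigma_loc = 0, seed = 3)
  set.seed(3)
  tr <- simulate_trajectory(cfg, length = 5000L)
  steps <- sqrt(rowSums(diff(tr$coords)^2))
  expect_lt(abs(mean(steps) - 1), 0.02)
})

test_that("confined motion stays near its anchor", {
  cfg <- simulation_config(states = "confined", kappa = 0.5, sigma_c = 0.25,
                           sigma_loc = 0, seed = 4)
  set.seed(4)
  tr <- simulate_trajectory(cfg, length = 5000L)
  # stationary spread of the OU-like recursion stays bounded (no diffusion)
  expect_lt(max(abs(tr$coords)), 5)
})

test_that("datasets are seed-reproducible byte for byte and respect bounds", {
  cfg <- simulation_preset("separable", n_tracks = 30L, seed = 12L)
  d1 <- withr::local_tempdir()
  a_train <- file.path(d1, "a_train.csv"); a_test <- file.path(d1, "a_test.csv")
  b_train <- file.path(d1, "b_train.csv"); b_test <- file.path(d1, "b_test.csv")
  simulate_dataset(cfg, 0.8, a_train, a_test)
  simulate_dataset(cfg, 0.8, b_train, b_test)
  expect_identical(readBin(a_train, "raw", file.size(a_train)),
                   readBin(b_train, "raw", file.size(b_train)))
  expect_identical(readBin(a_test, "raw", file.size(a_test)),
                   readBin(b_test, "raw", file.size(b_test)))

  ds <- simulate_dataset(cfg, 0.8)
  all_tr <- c(ds$train, ds$test)
  lens <- vapply(all_tr, trajectory_length, integer(1L))
  expect_true(all(lens >= 5L))
  expect_true(all(lens <= 135L))
  ids <- vapply(all_tr, `[[`, character(1L), "track_id")
  expect_false(anyDuplicated(ids) > 0)
  expect_length(ds$train, 24L)
  expect_length(ds$test, 6L)
  expect_error(simulate_dataset(simulation_config(n_tracks = 1L), 0.5),
               "n_tracks >= 2")
})

test_that("long-run class balance approaches the dwell-process expectation", {
  # four states with equal mean dwell: stationary share of 'directed' is 1/4
  cfg <- simulation_preset("separable", n_tracks = 150L, mean_length = 60,
                           seed = 5L)
  ds <- simulate_dataset(cfg, 1.0)
  labs <- unlist(lapply(ds$train, `[[`, "labels"))
  expect_lt(abs(mean(labs) - 0.25), 0.05)
})

test_that("simulation_config validates kinetic parameters", {
  expect_error(simulation_config(kappa = 0), "kappa")
  expect_error(simulation_config(kappa = 1.5), "kappa")
  expect_error(simulation_config(v = -1), "non-negative")
  expect_error(simulation_config(min_length = 10, max_length = 5), "max_length")
  expect_error(simulation_config(mean_dwell = 0.5), "mean_dwell")
  expect_error(simulation_config(states = "ballistic"), "arg")
})
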