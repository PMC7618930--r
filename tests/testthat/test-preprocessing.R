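test_that("window_spec validates its fields", {
  sp <- window_spec()
  expect_equal(sp$W, 8L)
  expect_equal(sp$step, 2L)
  expect_equal(sp$center_len, 4L)
  expect_equal(sp$center_off, 2L)
  expect_error(window_spec(W = 3), "W must be")
  expect_error(window_spec(W = 10), "divisible by 4")
  expect_error(window_spec(step = 0), "step")
  expect_error(window_spec(step = 8, center_fraction = 0.5), "gaps")
  expect_error(window_spec(center_fraction = 0), "center_fraction")
})

test_that("padding repeats the last point, labels the tail not_moving, and is idempotent", {
  tr <- trajectory("t", 0:4, cbind(1:5, 11:15), labels = c(1L, 1L, 0L, 0L, 1L))
  p <- pad_trajectory(tr, 8L)
  expect_equal(nrow(p$coords), 8L)
  for (i in 6:8) expect_equal(p$coords[i, ], p$coords[5L, ])
  expect_identical(p$valid_mask, c(rep(TRUE, 5), rep(FALSE, 3)))
  expect_identical(p$labels, c(tr$labels, 0L, 0L, 0L))

  # already long enough: unchanged, all-true mask
  tr8 <- random_trajectory(L = 8L)
  p8 <- pad_trajectory(tr8, 8L)
  expect_identical(p8$coords, tr8$coords)
  expect_true(all(p8$valid_mask))

  # degenerate single point
  tr1 <- trajectory("one", 0L, cbind(2, 3))
  p1 <- pad_trajectory(tr1, 8L)
  expect_equal(nrow(unique(p1$coords)), 1L)
  expect_identical(p1$valid_mask, c(TRUE, rep(FALSE, 7)))

  # idempotence: padding an already-padded set of coords changes nothing
  tr_padded <- trajectory("p", 0:7, p$coords)
  expect_identical(pad_trajectory(tr_padded, 8L)$coords, p$coords)

  expect_error(pad_trajectory(tr, 0L), "W must be")
})

test_that("window enumeration matches the spec'd starts and snaps the final window", {
  sp <- window_spec()
  w8 <- enumerate_windows(8L, sp)
  expect_length(w8, 1L)
  expect_equal(w8[[1]]$start, 0L)
  expect_true(all(w8[[1]]$weight_mask))

  w12 <- enumerate_windows(12L, sp)
  expect_equal(vapply(w12, `[[`, integer(1L), "start"), c(0L, 2L, 4L))

  w11 <- enumerate_windows(11L, sp)
  expect_equal(vapply(w11, `[[`, integer(1L), "start"), c(0L, 2L, 3L))

  expect_error(enumerate_windows(7L, sp), "pad")
})

test_that("weight masks reproduce the brute-force contribution oracle for L in 8..60", {
  sp <- window_spec()
  for (L in 8:60) {
    oc <- oracle_window_pairs(L)
    wins <- enumerate_windows(L, sp)
    expect_equal(vapply(wins, `[[`, integer(1L), "start"), oc$starts,
                 info = sprintf("starts at L=%d", L))
    got <- do.call(rbind, lapply(seq_along(wins), function(i) {
      pts <- wins[[i]]$start + which(wins[[i]]$weight_mask) - 1L
      cbind(point = pts, window = i)
    }))
    expect_equal(got[order(got[, "point"], got[, "window"]), , drop = FALSE],
                 oc$pairs[order(oc$pairs[, "point"], oc$pairs[, "window"]), , drop = FALSE],
                 info = sprintf("pairs at L=%d", L))
    covered <- sort(unique(got[, "point"]))
    expect_identical(covered, 0:(L - 1L), info = sprintf("coverage at L=%d", L))
  }
})

test_that("origin normalization is exact and translation invariant", {
  expect_equal(normalize_window(cbind(c(3, 4), c(4, 4))),
               cbind(c(0, 1), c(0, 0)), ignore_attr = TRUE)
  expect_true(all(normalize_window(matrix(5, 8, 2)) == 0))
  set.seed(21)
  for (i in 1:200) {
    coords <- matrix(rnorm(16, sd = 10), 8, 2)
    offset <- rnorm(2, sd = 1e3)
    shifted <- sweep(coords, 2L, offset, "+")
    expect_equal(normalize_window(shifted), normalize_window(coords),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(unname(normalize_window(coords)[1L, ]), c(0, 0))
  }
})

test_that("polar conversion is exact on axes, zero at origin, and invertible", {
  expect_equal(to_polar(cbind(1, 0)), cbind(1, 0), ignore_attr = TRUE)
  expect_equal(to_polar(cbind(0, 1)), cbind(1, pi / 2), ignore_attr = TRUE)
  expect_equal(to_polar(cbind(0, 0)), cbind(0, 0), ignore_attr = TRUE)
  set.seed(22)
  for (i in 1:200) {
    disp <- rbind(c(0, 0), matrix(rnorm(14, sd = 5), 7, 2))
    rt <- to_polar(disp)
    expect_true(all(rt[, 1L] >= 0))
    expect_true(all(rt[, 2L] > -pi & rt[, 2L] <= pi))
    back <- cbind(rt[, 1L] * cos(rt[, 2L]), rt[, 1L] * sin(rt[, 2L]))
    expect_lt(max(abs(back - disp)), 1e-9)
  }
})

test_that("build_features composes pad, enumerate, normalize and polar correctly", {
  sp <- window_spec()
  tr5 <- random_trajectory(L = 5L)
  wins5 <- build_features(tr5, sp, "polar")
  expect_length(wins5, 1L)
  expect_equal(attr(wins5, "n_original"), 5L)

  tr12 <- random_trajectory(L = 12L)
  wins12 <- build_features(tr12, sp, "cartesian")
  expect_equal(vapply(wins12, `[[`, integer(1L), "start"), c(0L, 2L, 4L))

  # first feature column is the origin in both coordinate systems
  for (w in c(wins5, wins12)) expect_equal(unname(w$features[, 1L]), c(0, 0))

  # axis-aligned motion: r equals x where y = 0, x >= 0
  tr_axis <- trajectory("ax", 0:7, cbind(c(0, 1, 2, 3, 4, 5, 6, 7), 0))
  cart <- build_features(tr_axis, sp, "cartesian")[[1]]$features
  pol <- build_features(tr_axis, sp, "polar")[[1]]$features
  expect_equal(pol[1L, ], cart[1L, ])
  expect_true(all(pol[2L, ] == 0))

  # per-window normalization uses the window's own first point
  w3 <- build_features(tr12, sp, "cartesian")[[3]]
  manual <- t(sweep(tr12$coords[5:12, ], 2L, tr12$coords[5L, ], "-"))
  expect_equal(unname(w3$features), unname(manual))
})

test_that("whole-trajectory translation changes no feature value", {
  set.seed(23)
  tr <- random_trajectory(L = 20L)
  shifted <- trajectory(tr$track_id, tr$frames,
                        sweep(tr$coords, 2L, c(1234.5, -987.6), "+"))
  for (cs in c("cartesian", "polar")) {
    a <- build_features(tr, window_spec(), cs)
    b <- build_features(shifted, window_spec(), cs)
    for (i in seq_along(a))
      expect_equal(a[[i]]$features, b[[i]]$features, tolerance = 1e-9)
  }
})
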