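test_that("interpolation weights follow the decay formula", {
  expect_equal(tlsi_weight(10, 3, 1, 0), 1)
  expect_equal(tlsi_weight(10, 3, 0, 2), 0)
  expect_equal(tlsi_weight(5, 4, 0.8, 0.5), 0.8 * exp(-0.5), tolerance = 1e-12)
  expect_equal(tlsi_weight(5, 4, 0.8, 0.5), 0.485225, tolerance = 1e-6)
  # strictly decreasing in distance, linear in confidence
  d <- tlsi_weight(0, 1:5, 1, 0.3)
  expect_true(all(diff(d) < 0))
  expect_equal(tlsi_weight(0, 2, 0.6, 0.3), 0.6 * tlsi_weight(0, 2, 1, 0.3))
  expect_error(tlsi_weight(0, 1, 0.5, -1), ">= 0")
  expect_error(tlsi_weight(0, 1, 1.5, 1), "\\[0, 1\\]")
})

test_that("imputation reproduces hand-computed cases", {
  # no missing joints: identity
  s <- random_occluded_seq(n_missing = 0L, seed = 3)
  expect_identical(tlsi_impute(s)$coords, s$coords)
  # symmetric equal-confidence neighbours give the exact midpoint
  coords <- array(0, dim = c(3, 1, 2))
  coords[1, 1, ] <- c(0, 0); coords[3, 1, ] <- c(2, 2)
  conf <- matrix(c(0.7, 0, 0.7), 3, 1)
  s <- pose_sequence_2d(coords, conf)
  for (lt in c(0, 0.5, 3)) {
    out <- tlsi_impute(s, window_halfwidth = 2L, lambda_t = lt)
    expect_equal(out$coords[2, 1, ], c(1, 1), tolerance = 1e-12)
  }
  # asymmetric distances and confidences, evaluated by hand:
  # w1 = 0.8 e^{-0.5}, w2 = 0.4 e^{-1}; p = w2 (3,3) / (w1 + w2)
  coords <- array(0, dim = c(4, 1, 2))
  coords[1, 1, ] <- c(0, 0); coords[4, 1, ] <- c(3, 3)
  conf <- matrix(c(0.8, 0, 0, 0.4), 4, 1)
  s <- pose_sequence_2d(coords, conf)
  out <- tlsi_impute(s, window_halfwidth = 3L, lambda_t = 0.5)
  w1 <- 0.8 * exp(-0.5); w2 <- 0.4 * exp(-1)
  expect_equal(out$coords[2, 1, ], rep(3 * w2 / (w1 + w2), 2),
               tolerance = 1e-12)
  expect_equal(out$coords[2, 1, 1], 0.6981, tolerance = 1e-4)
})

test_that("imputation matches the brute-force oracle on random cases", {
  for (rep in 1:60) {
    s <- random_occluded_seq(F_ = 10L, J = 4L, n_missing = sample(0:2, 1),
                             seed = rep)
    out <- tlsi_impute(s, window_halfwidth = 3L, lambda_t = 0.5)
    ref <- o_tlsi_impute(s$coords, s$confidence, s$observed, 3L, 0.5)
    expect_equal(out$coords, ref, tolerance = 1e-10)
    expect_true(all(out$observed))
  }
})

test_that("imputed points stay in the neighbours' bounding box and the
           large-decay limit is the nearest observed neighbour", {
  for (rep in 1:40) {
    s <- random_occluded_seq(F_ = 12L, J = 5L, n_missing = 2L, seed = 100 + rep)
    out <- tlsi_impute(s, window_halfwidth = 4L, lambda_t = 0.7)
    for (j in 1:5) {
      for (f in which(!s$observed[, j])) {
        ok <- which(s$observed[, j])
        nb <- ok[abs(ok - f) <= 4L]
        if (!length(nb)) nb <- ok
        for (c in 1:2) {
          rng <- range(s$coords[nb, j, c])
          expect_gte(out$coords[f, j, c], rng[1] - 1e-10)
          expect_lte(out$coords[f, j, c], rng[2] + 1e-10)
        }
      }
    }
    nn <- o_nearest_neighbour(s$coords, s$confidence, s$observed)
    far <- tlsi_impute(s, window_halfwidth = 12L, lambda_t = 50)
    expect_equal(far$coords, nn, tolerance = 1e-6)
  }
})

test_that("unobservable joints trigger the fallback chain", {
  coords <- array(rnorm(12), dim = c(6, 1, 2))
  conf <- matrix(c(1, 0, 0, 0, 0, 0), 6, 1)
  coords[2:6, 1, ] <- 0
  s <- pose_sequence_2d(coords, conf)
  # only neighbour is far outside the window: fallback widens and succeeds
  out <- tlsi_impute(s, window_halfwidth = 1L)
  expect_equal(out$coords[6, 1, ], coords[1, 1, ])
  # joint never observed anywhere: hard error
  conf0 <- matrix(0, 6, 1)
  s0 <- pose_sequence_2d(array(0, dim = c(6, 1, 2)), conf0)
  expect_error(tlsi_impute(s0), "uninterpolatable")
})

test_that("trend extraction equals the telescoped closed form", {
  expect_equal(ttep_trend(matrix(c(0, 1, 2), 3, 1)), 1)
  expect_equal(ttep_trend(matrix(c(0, 1, 3), 3, 1)), 1.5)
  expect_equal(ttep_trend(matrix(5, 4, 2)), c(0, 0))
  expect_error(ttep_trend(matrix(1, 1, 2)), "at least 2")
  set.seed(11)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    arr <- array(rnorm(k * 3 * 2), dim = c(k, 3, 2))
    expect_equal(ttep_trend(arr), (arr[k, , ] - arr[1, , ]) / (k - 1),
                 tolerance = 1e-12)
    expect_equal(ttep_trend(arr), o_ttep_trend(arr), tolerance = 1e-12)
  }
})

test_that("padding extrapolates trends in both modes", {
  # linear 1-joint 1-axis sequence X_i = i, i = 1..5
  lin <- array(1:5, dim = c(5, 1, 1))
  pad <- ttep_pad(lin, k = 2L, P = 2L, head_mode = "continuity")
  expect_equal(as.numeric(pad$coords[, 1, 1]), c(-1, 0, 1, 2, 3, 4, 5, 6, 7))
  expect_equal(pad$original_length, 5L)
  # published head formula adds the trend: pads (3, 2) for p = 2, 1
  padp <- ttep_pad(lin, k = 2L, P = 2L, head_mode = "as_printed")
  expect_equal(as.numeric(padp$coords[, 1, 1]), c(3, 2, 1, 2, 3, 4, 5, 6, 7))
  # tail pads agree between modes
  expect_equal(padp$coords[8:9, , ], pad$coords[8:9, , ])
  # constant sequences pad with the boundary value in both modes
  con <- array(4, dim = c(6, 2, 3))
  for (mode in c("continuity", "as_printed")) {
    pc <- ttep_pad(con, k = 3L, P = 4L, head_mode = mode)
    expect_true(all(pc$coords == 4))
  }
  # central frames always equal the source exactly
  set.seed(2)
  arr <- array(rnorm(8 * 3 * 2), dim = c(8, 3, 2))
  pr <- ttep_pad(arr, k = 3L, P = 3L)
  expect_identical(pr$coords[4:11, , ], arr)
  expect_error(ttep_pad(arr[1:2, , , drop = FALSE], k = 3L, P = 1L), "F >= k")
  expect_identical(ttep_pad(arr, k = 3L, P = 0L)$coords, arr)
})

test_that("continuity padding keeps exactly linear sequences exactly linear", {
  set.seed(13)
  for (rep in 1:20) {
    J <- sample(2:4, 1); F_ <- sample(5:9, 1); P <- sample(1:4, 1)
    a <- matrix(rnorm(J * 3), J, 3)
    b <- matrix(rnorm(J * 3), J, 3)
    arr <- array(0, dim = c(F_, J, 3))
    for (f in seq_len(F_)) arr[f, , ] <- a + f * b
    pad <- ttep_pad(arr, k = sample(2:4, 1), P = P, head_mode = "continuity")
    for (f in seq_len(F_ + 2 * P)) {
      expect_lt(max(abs(pad$coords[f, , ] - (a + (f - P) * b))), 1e-10)
    }
  }
})
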