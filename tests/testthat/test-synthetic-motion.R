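lay17 <- default_joint_layout()

test_that("generator degenerate cases match their construction", {
  lay <- chain_layout(4L)
  # zero amplitude, zero noise, fixed drift: exactly linear trajectories
  p <- motion_params(n_frames = 10L, amplitude_range = c(0, 0),
                     drift_range = c(0.3, 0.3), noise_sd = 0)
  g <- gen_pose_sequence(lay, p, seed = 5)
  for (j in 1:4) {
    for (c in 1:3) {
      expect_equal(diff(g$pose3d$coords[, j, c]), rep(0.3, 9),
                   tolerance = 1e-12)
    }
  }
  # fully degenerate: constant sequence
  p0 <- motion_params(n_frames = 6L, amplitude_range = c(0, 0),
                      drift_range = c(0, 0), noise_sd = 0)
  g0 <- gen_pose_sequence(lay, p0, seed = 5)
  expect_equal(apply(g0$pose3d$coords, c(2, 3), function(v) max(v) - min(v)),
               matrix(0, 4, 3))
  # 2D view is the orthographic projection with unit confidence
  expect_equal(g$pose2d$coords, g$pose3d$coords[, , 1:2])
  expect_true(all(g$pose2d$confidence == 1))
  expect_error(motion_params(n_frames = 3L), ">= 4")
})

test_that("generation is a pure function of (params, seed)", {
  p <- motion_params(n_frames = 12L)
  a <- gen_pose_sequence(lay17, p, seed = 99)
  b <- gen_pose_sequence(lay17, p, seed = 99)
  expect_identical(a$pose3d$coords, b$pose3d$coords)
  expect_identical(a$pose2d$coords, b$pose2d$coords)
  c_ <- gen_pose_sequence(lay17, p, seed = 100)
  expect_false(identical(a$pose3d$coords, c_$pose3d$coords))
})

test_that("occlusion drops exactly the requested joints per frame", {
  p <- motion_params(n_frames = 20L, noise_sd = 0)
  s <- gen_pose_sequence(lay17, p, seed = 1)$pose2d
  expect_identical(apply_occlusion(s, 0L), s)
  full <- apply_occlusion(s, 17L, seed = 2)
  expect_false(any(full$observed))
  for (n in c(1L, 4L, 9L)) {
    for (mode in c("iid", "block")) {
      occ <- apply_occlusion(s, n, seed = 3, mode = mode)
      expect_equal(rowSums(!occ$observed), rep(n, 20))
      expect_true(all(occ$coords[!array(rep(occ$observed, 2),
                                        dim = dim(occ$coords))] == 0))
      expect_true(all(occ$confidence[!occ$observed] == 0))
    }
  }
  # block mode drops contiguous joint runs
  occ <- apply_occlusion(s, 5L, seed = 4, mode = "block")
  runs <- apply(!occ$observed, 1, function(m) {
    w <- which(m); all(diff(w) == 1)
  })
  expect_true(all(runs))
  expect_error(apply_occlusion(s, 18L), "\\[0, J\\]")
})

test_that("generator moments match the specification", {
  # empirical check across replicates: drift slope and amplitude stay within
  # 3 standard errors of the configured values
  p <- motion_params(n_frames = 40L, amplitude_range = c(1, 1),
                     frequency_range = c(1, 1), drift_range = c(0.05, 0.05),
                     noise_sd = 0)
  lay <- chain_layout(3L)
  slopes <- replicate(200, {
    g <- gen_pose_sequence(lay, p, seed = sample.int(1e6, 1))
    mean(apply(g$pose3d$coords, c(2, 3), function(v) {
      stats::coef(stats::lm(v ~ seq_along(v)))[2]
    }))
  })
  expect_lt(abs(mean(slopes) - 0.05), 3 * stats::sd(slopes) / sqrt(200) + 1e-3)
  amps <- replicate(200, {
    g <- gen_pose_sequence(lay, p, seed = sample.int(1e6, 1))
    v <- g$pose3d$coords[, 1, 1]
    det <- stats::residuals(stats::lm(v ~ seq_along(v)))
    (max(det) - min(det)) / 2
  })
  # detrended half-range of a unit sinusoid is close to 1
  expect_lt(abs(mean(amps) - 1), 3 * stats::sd(amps) / sqrt(200) + 0.05)
})

test_that("two-class datasets carry the injected effect and only it", {
  eff <- class_effect(c(2L, 3L), effect_size = 3, n_per_class = 30L)
  p <- motion_params(n_frames = 30L, noise_sd = 0, drift_range = c(0, 0))
  lay <- chain_layout(4L)
  ds <- gen_classification_dataset(lay, eff, p, seed = 7)
  expect_equal(sum(ds$labels), 30L)
  expect_equal(length(ds$sequences), 60L)
  disp <- function(s, j) {
    d <- diff(s$coords[, j, 1])
    mean(abs(d))
  }
  m0 <- sapply(ds$sequences[ds$labels == 0], disp, j = 2)
  m1 <- sapply(ds$sequences[ds$labels == 1], disp, j = 2)
  # mean per-frame displacement at a discriminative joint scales ~ effect
  expect_gt(mean(m1) / mean(m0), 2.2)
  expect_lt(mean(m1) / mean(m0), 3.8)
  # non-discriminative joints identically distributed (ratio ~ 1)
  n0 <- sapply(ds$sequences[ds$labels == 0], disp, j = 4)
  n1 <- sapply(ds$sequences[ds$labels == 1], disp, j = 4)
  expect_lt(abs(mean(n1) / mean(n0) - 1), 0.35)
  # determinism and bookkeeping
  ds2 <- gen_classification_dataset(lay, eff, p, seed = 7)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$sequences[[1]]$coords, ds2$sequences[[1]]$coords)
  expect_error(class_effect(integer(0), effect_size = 2), "empty")
  small <- gen_classification_dataset(
    lay, class_effect(2L, 2, n_per_class = 5L), p, seed = 1)
  expect_equal(length(small$sequences), 10L)
  expect_equal(sum(small$labels), 5L)
})
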