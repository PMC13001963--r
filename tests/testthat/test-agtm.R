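lay17 <- default_joint_layout()

test_that("static adjacency encodes the tree", {
  A <- build_static_adjacency(chain_layout(3L), self_loops = FALSE)
  expect_equal(A, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  expect_equal(build_static_adjacency(joint_layout("a", -1L)), matrix(1))
  A17 <- build_static_adjacency(lay17)
  expect_identical(A17, t(A17))
  expect_true(all(diag(A17) == 1))
  expect_equal(sum(A17) - 17, 2 * 16)       # 16 undirected tree edges
})

test_that("dynamic adjacency matches hand softmax and the oracle", {
  # zero query projection: uniform attention
  Ad <- dynamic_adjacency(matrix(rnorm(8), 4, 2), matrix(0, 2, 3),
                          matrix(rnorm(6), 2, 3))
  expect_equal(Ad, matrix(0.25, 4, 4), tolerance = 1e-12)
  # J=2, C=dk=1, X=(1,2), Wq=Wk=1: scores [[1,2],[2,4]]
  Ad <- dynamic_adjacency(matrix(c(1, 2), 2, 1), matrix(1), matrix(1))
  expect_equal(Ad[1, ], o_softmax_row(c(1, 2)), tolerance = 1e-12)
  expect_equal(Ad[2, ], o_softmax_row(c(2, 4)), tolerance = 1e-12)
  expect_equal(Ad[1, 1], 0.2689, tolerance = 1e-3)
  expect_equal(Ad[2, 1], 0.1192, tolerance = 1e-3)
  set.seed(61)
  for (rep in 1:100) {
    J <- sample(2:6, 1); C <- sample(1:4, 1); dk <- sample(1:4, 1)
    X <- matrix(rnorm(J * C, sd = 2), J, C)
    Wq <- matrix(rnorm(C * dk), C, dk)
    Wk <- matrix(rnorm(C * dk), C, dk)
    Ad <- dynamic_adjacency(X, Wq, Wk)
    expect_equal(rowSums(Ad), rep(1, J), tolerance = 1e-6)
    expect_true(all(Ad > 0))
    expect_equal(Ad, o_dynamic_adjacency(X, Wq, Wk), tolerance = 1e-8)
  }
})

test_that("adjacency fusion is a convex combination with exact row sums", {
  A0 <- matrix(c(1, 0, 0, 1), 2, 2)
  Ad <- matrix(0.5, 2, 2)
  expect_equal(fuse_adjacency(A0, Ad, 1), A0)
  expect_equal(fuse_adjacency(A0, Ad, 0), Ad)
  expect_equal(fuse_adjacency(A0, Ad, 0.5),
               matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2))
  expect_error(fuse_adjacency(A0, Ad, 1.2), "\\[0, 1\\]")
  set.seed(62)
  for (rep in 1:50) {
    J <- sample(2:6, 1)
    A0 <- build_static_adjacency(chain_layout(J))
    X <- matrix(rnorm(J * 3), J, 3)
    Ad <- dynamic_adjacency(X, matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2))
    lam <- runif(1)
    Af <- fuse_adjacency(A0, Ad, lam)
    expect_equal(rowSums(Af), lam * rowSums(A0) + (1 - lam),
                 tolerance = 1e-10)
  }
})

test_that("graph convolution and CCI block match explicit computations", {
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(graph_conv(diag(2), X, diag(2)), X)
  expect_equal(graph_conv(diag(2), matrix(0, 2, 2), diag(2)),
               matrix(0, 2, 2))
  set.seed(63)
  for (rep in 1:50) {
    J <- sample(2:5, 1); C <- sample(1:3, 1); Cp <- sample(1:3, 1)
    A <- matrix(runif(J * J), J, J)
    X <- matrix(rnorm(J * C), J, C)
    W <- matrix(rnorm(C * Cp), C, Cp)
    expect_equal(graph_conv(A, X, W), o_graph_conv(A, X, W),
                 tolerance = 1e-10)
  }
  expect_error(graph_conv(diag(3), matrix(0, 2, 2), diag(2)),
               "dimension mismatch")
  H <- matrix(rnorm(10), 5, 2)
  expect_identical(cci_block(H), H)
  expect_error(cci_block(matrix(NaN, 1, 2)), "NaN")
})

test_that("stacking, pooling and the classification head are exact", {
  frames <- list(matrix(1:2, 2, 1), matrix(3:4, 2, 1))
  H <- stack_temporal(frames)
  expect_equal(dim(H), c(2L, 2L, 1L))
  expect_equal(H[2, , 1], c(3, 4))
  expect_equal(global_pool(H), 2.5)
  expect_equal(stack_temporal(frames[1])[1, , ], frames[[1]][, 1])
  # linearity of pooling
  H2 <- H + 1
  expect_equal(global_pool(H + H2), global_pool(H) + global_pool(H2))
  expect_error(stack_temporal(list()), "empty")
  # zero-weight head: probability exactly 0.5; monotone in the logit
  expect_equal(classify(c(1, 2)), 0.5)
  w <- list(W1 = diag(2), b1 = matrix(0, 1, 2),
            W2 = matrix(c(1, 1), 2, 1), b2 = matrix(0))
  expect_gt(classify(c(2, 2), w), classify(c(1, 1), w))
  # hand-computed forward: relu((1,0)) = (1,0); logit = 1
  expect_equal(classify(c(1, 0), w), 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("permutation equivariance of the graph convolution", {
  set.seed(64)
  J <- 5L
  A <- matrix(runif(25), J, J)
  X <- matrix(rnorm(15), J, 3)
  W <- matrix(rnorm(6), 3, 2)
  pi_ <- sample(J)
  P <- diag(J)[pi_, ]
  lhs <- graph_conv(P %*% A %*% t(P), P %*% X, W)
  rhs <- P %*% graph_conv(A, X, W)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("classification metrics follow the confusion-count formulas", {
  r <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(r$accuracy, r$precision, r$recall, r$f1), rep(1, 4))
  # TP=8 FP=2 FN=3 TN=7, evaluated by hand
  y <- c(rep(1, 11), rep(0, 9))
  yh <- c(rep(1, 8), rep(0, 3), rep(1, 2), rep(0, 7))
  r <- classification_metrics(y, yh)
  expect_equal(r$tp, 8L); expect_equal(r$fp, 2L)
  expect_equal(r$fn, 3L); expect_equal(r$tn, 7L)
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 8 / 11, tolerance = 1e-12)
  expect_equal(r$f1, 2 * 0.8 * (8 / 11) / (0.8 + 8 / 11), tolerance = 1e-12)
  # degenerate all-negative predictions: flagged zeros, never NaN
  r0 <- classification_metrics(c(1, 0, 1), c(0, 0, 0))
  expect_equal(r0$recall, 0)
  expect_equal(r0$f1, 0)
  expect_true(all(c("precision", "f1") %in% r0$degenerate))
  set.seed(65)
  for (rep in 1:50) {
    y <- rbinom(20, 1, 0.5); yh <- rbinom(20, 1, 0.5)
    ref <- o_clf_metrics(y, yh)
    r <- classification_metrics(y, yh)
    expect_equal(r$accuracy, ref$accuracy)
    expect_equal(r$precision, ref$precision)
    expect_equal(r$recall, ref$recall)
    expect_equal(r$f1, ref$f1)
  }
  expect_error(classification_metrics(c(1, 0), c(1)), "length mismatch")
  expect_error(classification_metrics(c(1, 2), c(1, 0)), "binary")
})

test_that("skeleton normalisation centres the root and fixes the scale", {
  g <- gen_pose_sequence(lay17, motion_params(n_frames = 8L), seed = 3)
  nc <- normalize_skeleton(g$pose3d$coords, lay17)
  expect_equal(nc[, 1, ], matrix(0, 8, 3))     # pelvis is the root
  # the time-averaged pose has unit mean bone length after normalisation
  mp <- apply(nc, c(2, 3), mean)
  d <- mp[lay17$edges[, 1], ] - mp[lay17$edges[, 2], ]
  expect_equal(mean(sqrt(rowSums(d^2))), 1, tolerance = 1e-10)
})

test_that("training is deterministic and rejects single-class data", {
  eff <- class_effect(c(2L, 5L, 8L, 9L), effect_size = 3, n_per_class = 4L)
  ds <- gen_classification_dataset(lay17, eff,
                                   motion_params(n_frames = 8L), seed = 2)
  cfg <- model_config(clf_epochs = 2L, clf_lr = 0.005, gcn_dim = 8L, dk = 4L)
  m1 <- train_agtm(ds, cfg, lay17, seed = 5, restarts = 0L)
  m2 <- train_agtm(ds, cfg, lay17, seed = 5, restarts = 0L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$head$W2, m2$params$head$W2)
  p1 <- predict_agtm(m1, ds)
  expect_true(all(p1$prob > 0 & p1$prob < 1))
  expect_identical(p1$label, as.integer(p1$prob >= 0.5))
  bad <- labeled_dataset(ds$sequences[ds$labels == 1],
                         ds$labels[ds$labels == 1],
                         require_both_classes = FALSE)
  expect_error(train_agtm(bad, cfg, lay17), "single-class")
  # checkpoint round trip preserves scores
  p <- tempfile(fileext = ".json")
  write_model(m1, p)
  m3 <- read_model(p)
  expect_equal(predict_agtm(m3, ds)$prob, p1$prob, tolerance = 1e-12)
  unlink(p)
})
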