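# Independent brute-force oracles: deliberately naive loop implementations
# of every formula-level operation, kept free of any package internals so
# they can arbitrate the optimised code paths.

o_softmax_row <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

o_cross_attention <- function(E1, E2) {
  n <- nrow(E1); d <- ncol(E1)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    scores <- numeric(n)
    for (j in seq_len(n)) scores[j] <- sum(E1[i, ] * E2[j, ]) / sqrt(d)
    a <- o_softmax_row(scores)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + a[j] * E2[j, ]
  }
  out
}

o_dynamic_adjacency <- function(Xt, Wq, Wk) {
  J <- nrow(Xt); dk <- ncol(Wq)
  Q <- Xt %*% Wq; K <- Xt %*% Wk
  A <- matrix(0, J, J)
  for (i in seq_len(J)) {
    s <- numeric(J)
    for (j in seq_len(J)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    A[i, ] <- o_softmax_row(s)
  }
  A
}

o_graph_conv <- function(A, X, W) {
  J <- nrow(A); Cp <- ncol(W)
  out <- matrix(0, J, Cp)
  for (i in seq_len(J)) {
    for (c in seq_len(Cp)) {
      acc <- 0
      for (j in seq_len(J)) {
        for (k in seq_len(ncol(X))) acc <- acc + A[i, j] * X[j, k] * W[k, c]
      }
      out[i, c] <- max(acc, 0)
    }
  }
  out
}

o_ttep_trend <- function(frames3d) {
  k <- dim(frames3d)[1]
  acc <- frames3d[1, , , drop = FALSE] * 0
  for (i in seq_len(k - 1L)) {
    acc <- acc + frames3d[i + 1L, , , drop = FALSE] - frames3d[i, , , drop = FALSE]
  }
  array(acc / (k - 1L), dim = dim(frames3d)[2:3])
}

o_tlsi_impute <- function(coords, conf, obs, w, lt) {
  F_ <- dim(coords)[1]; J <- dim(coords)[2]
  out <- coords
  for (j in seq_len(J)) {
    for (f in seq_len(F_)) {
      if (obs[f, j]) next
      nb <- integer(0)
      for (f2 in seq_len(F_)) {
        if (obs[f2, j] && abs(f2 - f) <= w) nb <- c(nb, f2)
      }
      ws <- exp(-lt * abs(nb - f)) * conf[nb, j]
      if (!length(nb) || sum(ws) == 0) {
        nb <- which(obs[, j])
        ws <- exp(-lt * abs(nb - f)) * conf[nb, j]
      }
      num <- c(0, 0)
      for (i in seq_along(nb)) num <- num + ws[i] * coords[nb[i], j, ]
      out[f, j, ] <- num / sum(ws)
    }
  }
  out
}

o_mpjpe <- function(p, t_) {
  acc <- 0; n <- 0
  for (f in seq_len(dim(p)[1])) {
    for (j in seq_len(dim(p)[2])) {
      acc <- acc + sqrt(sum((p[f, j, ] - t_[f, j, ])^2))
      n <- n + 1
    }
  }
  acc / n
}

o_pck <- function(p, t_, thr) {
  acc <- 0; n <- 0
  for (f in seq_len(dim(p)[1])) {
    for (j in seq_len(dim(p)[2])) {
      acc <- acc + as.numeric(sqrt(sum((p[f, j, ] - t_[f, j, ])^2)) < thr)
      n <- n + 1
    }
  }
  acc / n
}

o_auc <- function(p, t_, grid) {
  mean(sapply(grid[grid > 0], function(tau) o_pck(p, t_, tau)))
}

o_clf_metrics <- function(y, yh) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && yh[i] == 1) tp <- tp + 1
    if (y[i] == 0 && yh[i] == 1) fp <- fp + 1
    if (y[i] == 1 && yh[i] == 0) fn <- fn + 1
    if (y[i] == 0 && yh[i] == 0) tn <- tn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(y), precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

# nearest observed neighbour of the same joint; ties at equal distance are
# confidence-weighted averages (the exact lambda_t -> Inf limit)
o_nearest_neighbour <- function(coords, conf, obs) {
  F_ <- dim(coords)[1]; J <- dim(coords)[2]
  out <- coords
  for (j in seq_len(J)) {
    ok <- which(obs[, j])
    for (f in which(!obs[, j])) {
      dmin <- min(abs(ok - f))
      near <- ok[abs(ok - f) == dmin]
      w <- conf[near, j]
      out[f, j, ] <- colSums(coords[near, j, , drop = FALSE] * w) / sum(w)
    }
  }
  out
}

# small random 2D sequence with occlusion, for property tests
random_occluded_seq <- function(F_ = 12L, J = 5L, n_missing = 1L, seed = 1L) {
  set.seed(seed)
  coords <- array(stats::rnorm(F_ * J * 2L), dim = c(F_, J, 2L))
  conf <- matrix(stats::runif(F_ * J, 0.2, 1), F_, J)
  s <- pose_sequence_2d(coords, conf)
  apply_occlusion(s, n_missing, seed = seed + 1L)
}

chain_layout <- function(J) {
  joint_layout(paste0("j", seq_len(J)), c(-1L, seq_len(J - 1L) - 1L))
}

toy_pose_config <- function(frames = 18L, epochs = 5L, ...) {
  model_config(dm = 8L, df = 16L, attention_heads = 2L, frames = frames,
               pad = 3L, segment_lengths = c(frames, 6L), epochs = epochs,
               lr = 0.01, lr_decay = 0.995, ...)
}
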