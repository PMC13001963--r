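# Adaptive graph topology skeleton classifier.
#
# Per time step t, node features X_t (J x C) drive a dynamic adjacency
#   A_d = Softmax((X_t W_q)(X_t W_k)^T / sqrt(d_k))
# which is fused with the static skeleton adjacency A_0 as
#   A_final = lambda A_0 + (1 - lambda) A_d,
# followed by a graph convolution H_t = sigma(A_final X_t W_f) and a
# residual channel-wise interaction block H_t + MLP(LN(H_t)). Frame
# features are stacked over time, pooled over time steps and joints, and
# classified by a two-layer head with a sigmoid output.

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Static skeleton adjacency
#'
#' Binary symmetric adjacency with 1 wherever two joints are connected in
#' the kinematic tree, plus an optional self-loop diagonal.
#'
#' @param layout a `joint_layout`.
#' @param self_loops add ones on the diagonal (default `TRUE`).
#' @return J x J binary matrix.
#' @export
build_static_adjacency <- function(layout, self_loops = TRUE) {
  stopifnot(inherits(layout, "joint_layout"))
  J <- layout$n_joints
  A <- matrix(0, J, J)
  if (nrow(layout$edges)) {
    A[layout$edges] <- 1
    A[layout$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  if (self_loops) diag(A) <- 1
  A
}

#' Attention-derived dynamic adjacency
#'
#' Row-wise softmax of the scaled score matrix
#' `(Xt Wq)(Xt Wk)^T / sqrt(dk)`; every row sums to 1 and all entries are
#' strictly positive.
#'
#' @param Xt J x C node feature matrix.
#' @param Wq,Wk C x dk query/key projection matrices.
#' @return J x J row-stochastic matrix.
#' @export
dynamic_adjacency <- function(Xt, Wq, Wk) {
  Xt <- as_mat(Xt); Wq <- as_mat(Wq); Wk <- as_mat(Wk)
  dk <- ncol(Wq)
  if (dk < 1L) stop("dk must be positive")
  if (ncol(Xt) != nrow(Wq) || ncol(Xt) != nrow(Wk)) stop("dimension mismatch")
  softmax_rows((Xt %*% Wq) %*% t(Xt %*% Wk) / sqrt(dk))
}

#' Fuse static and dynamic adjacency
#'
#' Elementwise convex combination `lambda * A0 + (1 - lambda) * Ad`.
#'
#' @param A0 static binary adjacency.
#' @param Ad dynamic row-stochastic adjacency.
#' @param lambda mixing weight in `[0, 1]`.
#' @return J x J matrix.
#' @export
fuse_adjacency <- function(A0, Ad, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (!all(dim(A0) == dim(Ad))) stop("shape mismatch")
  lambda * A0 + (1 - lambda) * Ad
}

#' Graph convolution
#'
#' `Ht = activation(A_final %*% Xt %*% Wf)`.
#'
#' @param A_final J x J adjacency.
#' @param Xt J x C node features.
#' @param Wf C x C' feature transform.
#' @param activation vectorised activation function (default ReLU).
#' @return J x C' matrix.
#' @export
graph_conv <- function(A_final, Xt, Wf, activation = function(x) pmax(x, 0)) {
  if (ncol(A_final) != nrow(Xt) || ncol(Xt) != nrow(Wf)) {
    stop("dimension mismatch")
  }
  activation(A_final %*% Xt %*% Wf)
}

#' Cross-node feature interaction block
#'
#' Residual channel-wise MLP `Ht + MLP(LayerNorm(Ht))`, applied per node
#' (no cross-node mixing). `weights = NULL` zero-initialises the MLP,
#' giving the exact identity.
#'
#' @param Ht J x C' matrix.
#' @param weights list (`ln_g`, `ln_b`, `W1`, `b1`, `W2`, `b2`) or `NULL`.
#' @return J x C' matrix.
#' @export
cci_block <- function(Ht, weights = NULL) {
  Ht <- as_mat(Ht)
  if (anyNA(Ht)) stop("NaN input")
  if (is.null(weights)) weights <- ffn_weights(ncol(Ht), ncol(Ht), zero = TRUE)
  run_plain(function(tape) {
    ag_ffn_block(tape, ag_leaf(tape, Ht), ag_wrap_params(tape, weights))
  })
}

#' Stack per-frame node features over time
#'
#' @param frames list of T equally shaped J x C' matrices.
#' @return T x J x C' array preserving order.
#' @export
stack_temporal <- function(frames) {
  if (!length(frames)) stop("empty frame list")
  dm <- dim(frames[[1L]])
  H <- array(0, dim = c(length(frames), dm[1], dm[2]))
  for (t in seq_along(frames)) {
    if (!all(dim(frames[[t]]) == dm)) stop("shape mismatch across frames")
    H[t, , ] <- frames[[t]]
  }
  H
}

#' Global average pooling over time steps and joints
#'
#' `g = 1/(T*J) * sum_t sum_j H[t, j, ]`; linear in H.
#'
#' @param H T x J x C' array.
#' @return numeric vector of length C'.
#' @export
global_pool <- function(H) {
  stopifnot(is.array(H), length(dim(H)) == 3L)
  if (prod(dim(H)) == 0L) stop("empty feature tensor")
  apply(H, 3L, mean)
}

#' Two-layer classification head
#'
#' `sigmoid(W2 relu(W1 g + b1) + b2)`; probability of class 1 in (0, 1).
#' Decision threshold is 0.5, with ties classified as class 1.
#'
#' @param g pooled feature vector.
#' @param weights list (`W1`, `b1`, `W2`, `b2`) or `NULL` (all-zero head,
#'   probability exactly 0.5).
#' @return probability of class 1.
#' @export
classify <- function(g, weights = NULL) {
  g <- matrix(as.numeric(g), nrow = 1L)
  if (is.null(weights)) weights <- asw_head_weights(ncol(g), ncol(g), zero = TRUE)
  z <- pmax(g %*% weights$W1 + matrix(weights$b1, 1), 0) %*% weights$W2 +
    weights$b2[1L]
  1 / (1 + exp(-z[1L]))
}

# --- model -------------------------------------------------------------------

#' Normalise a skeleton sequence
#'
#' Root-joint centring per frame plus division by the mean bone length of
#' the time-averaged pose (1 if degenerate). Measuring the scale on the
#' time-averaged skeleton rather than frame by frame matters: per-frame
#' bone lengths grow with motion amplitude, so a per-frame scale would
#' normalise away movement vigor -- often the very signal a clinical
#' contrast is built on -- while the time-averaged pose reflects body size
#' only (for a rigid skeleton it is the actual bone length, and detector
#' noise averages out).
#'
#' @param coords F x J x C array.
#' @param layout a `joint_layout`.
#' @return normalised F x J x C array.
#' @export
normalize_skeleton <- function(coords, layout) {
  root <- layout$root_index + 1L
  out <- coords
  for (c in seq_len(dim(coords)[3])) {
    out[, , c] <- coords[, , c] - coords[, root, c]
  }
  if (nrow(layout$edges)) {
    mean_pose <- apply(out, c(2, 3), mean)          # J x C time-averaged pose
    d <- mean_pose[layout$edges[, 1L], , drop = FALSE] -
      mean_pose[layout$edges[, 2L], , drop = FALSE]
    bl <- mean(sqrt(rowSums(d^2)))
    if (bl > 0) out <- out / bl
  }
  out
}

agtm_params <- function(C_in, config) {
  Cp <- config$gcn_dim
  dims <- c(C_in, rep(Cp, config$gcn_layers))
  layers <- lapply(seq_len(config$gcn_layers), function(l) {
    list(Wq = rmat(dims[l], config$dk), Wk = rmat(dims[l], config$dk),
         Wf = rmat(dims[l], dims[l + 1L]),
         cci = ffn_weights(dims[l + 1L], dims[l + 1L] * config$ffn_mult))
  })
  # small positive hidden bias keeps the head's ReLU units alive at the
  # start; a dead head (all-negative preactivations for every pooled input)
  # otherwise freezes training at the chance plateau for some inits
  list(layers = layers,
       head = list(W1 = rmat(Cp, Cp), b1 = matrix(0.1, 1, Cp),
                   W2 = rmat(Cp, 1), b2 = matrix(0, 1, 1)))
}

# Fused per-time-step graph layer over a stacked (T*J) x C input.
#
# For every time step t: Ad = softmax((Xt Wq)(Xt Wk)^T / sqrt(dk)),
# Af = lambda A0 + (1 - lambda) Ad, Ht = relu(Af Xt Wf). A single tape node
# with a hand-derived backward keeps the per-frame loop in raw matrix code
# instead of thousands of tiny tape nodes (interpreter overhead dominates
# otherwise on these 17 x C matrices).
ag_graph_layer <- function(tape, xall, Wq, Wk, Wf, A0, lambda, dk, T_, J) {
  Xv <- xall$value; Wqv <- Wq$value; Wkv <- Wk$value; Wfv <- Wf$value
  sdk <- sqrt(dk)
  Qa <- Xv %*% Wqv                      # projections batched over time
  Ka <- Xv %*% Wkv
  Ma <- matrix(0, nrow(Xv), ncol(Xv))
  Ads <- vector("list", T_)
  Afs <- vector("list", T_)
  for (t in seq_len(T_)) {
    rows <- ((t - 1L) * J + 1L):(t * J)
    S <- Qa[rows, , drop = FALSE] %*% t(Ka[rows, , drop = FALSE]) / sdk
    E <- exp(pmax(S - apply(S, 1L, max), -500))
    Ad <- E / rowSums(E)
    Af <- lambda * A0 + (1 - lambda) * Ad
    Ma[rows, ] <- Af %*% Xv[rows, , drop = FALSE]
    Ads[[t]] <- Ad
    Afs[[t]] <- Af
  }
  H <- Ma %*% Wfv
  pos <- H > 0
  ag_node(tape, pmax(H, 0), function(g) {
    R <- g * pos
    dWf <- t(Ma) %*% R
    dMa <- R %*% t(Wfv)
    dX <- matrix(0, nrow(Xv), ncol(Xv))
    dQa <- matrix(0, nrow(Qa), ncol(Qa))
    dKa <- matrix(0, nrow(Ka), ncol(Ka))
    for (t in seq_len(T_)) {
      rows <- ((t - 1L) * J + 1L):(t * J)
      Xt <- Xv[rows, , drop = FALSE]
      dM <- dMa[rows, , drop = FALSE]
      dAf <- dM %*% t(Xt)
      dX[rows, ] <- t(Afs[[t]]) %*% dM
      dAd <- (1 - lambda) * dAf
      Ad <- Ads[[t]]
      dS <- Ad * (dAd - rowSums(dAd * Ad)) / sdk
      dQa[rows, ] <- dS %*% Ka[rows, , drop = FALSE]
      dKa[rows, ] <- t(dS) %*% Qa[rows, , drop = FALSE]
    }
    dX <- dX + dQa %*% t(Wqv) + dKa %*% t(Wkv)
    ag_acc(xall, dX)
    ag_acc(Wq, t(Xv) %*% dQa)
    ag_acc(Wk, t(Xv) %*% dKa)
    ag_acc(Wf, dWf)
  })
}

# logit for one normalised sequence given as a (T*J) x C matrix leaf
agtm_logit <- function(tape, wp, xall, T_, J, A0, lambda, config) {
  h <- xall
  for (l in seq_along(wp$layers)) {
    lw <- wp$layers[[l]]
    h <- ag_graph_layer(tape, h, lw$Wq, lw$Wk, lw$Wf, A0, lambda,
                        config$dk, T_, J)
    h <- ag_ffn_block(tape, h, lw$cci)    # row-wise, so valid on the stack
  }
  g <- ag_colmeans(tape, h)
  hh <- ag_relu(tape, ag_add(tape, ag_matmul(tape, g, wp$head$W1), wp$head$b1))
  ag_add(tape, ag_matmul(tape, hh, wp$head$W2), wp$head$b2)
}

# Normalised node-feature matrix, (T*J) x C. With velocity = TRUE the
# per-frame joint displacements are appended as extra channels (the
# standard two-stream skeleton input: position + motion), doubling C.
seq_to_norm_mat <- function(s, layout, velocity = TRUE) {
  coords <- if (inherits(s, "pose_sequence_3d") ||
                inherits(s, "pose_sequence_2d")) s$coords else s
  nc <- normalize_skeleton(coords, layout)
  dm <- dim(nc)
  C <- if (velocity) 2L * dm[3] else dm[3]
  mat <- matrix(0, dm[1] * dm[2], C)
  for (t in seq_len(dm[1])) {
    rows <- ((t - 1L) * dm[2] + 1L):(t * dm[2])
    mat[rows, seq_len(dm[3])] <- nc[t, , ]
    if (velocity && t > 1L) {
      mat[rows, (dm[3] + 1L):C] <- nc[t, , ] - nc[t - 1L, , ]
    }
  }
  mat
}

#' Train the graph skeleton classifier
#'
#' Binary cross-entropy optimisation with Adam, per-sample updates, and a
#' milestone learning-rate schedule (`config$clf_lr` decayed by
#' `config$clf_gamma` at `config$clf_milestones`, over `config$clf_epochs`
#' epochs). Sequences are normalised (root centring and mean-bone-length
#' scaling) before training. Deterministic given `seed`.
#'
#' @param dataset a `labeled_dataset` of 2D or 3D sequences (both are
#'   accepted; the node feature dimension follows the input).
#' @param config a `model_config`.
#' @param layout a `joint_layout`.
#' @param seed integer seed.
#' @param verbose print a line per epoch.
#' @param restarts maximum reinitialisations when training ends with a
#'   final cross-entropy above `loss_target`. Per-sample optimisation of
#'   this small model occasionally lands in a poor basin (in the extreme,
#'   the chance plateau at log 2); reseeded restarts recover it
#'   deterministically, and the candidate with the lowest final training
#'   loss is returned. Selection uses training loss only -- no held-out
#'   data is consulted.
#' @param loss_target final training cross-entropy below which a fit is
#'   accepted without further restarts.
#' @return an object of class `agtm_model` with a training `history`.
#' @export
train_agtm <- function(dataset, config = model_config(),
                       layout = default_joint_layout(),
                       seed = config$seed, verbose = FALSE, restarts = 2L,
                       loss_target = 0.4) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(unique(dataset$labels)) < 2L) stop("single-class dataset")
  best <- NULL
  best_loss <- Inf
  for (attempt in 0L:max(0L, restarts)) {
    model <- train_agtm_once(dataset, config, layout,
                             seed = seed + 7919L * attempt, verbose = verbose)
    final <- mean(utils::tail(model$history$loss, 5L))
    if (final < best_loss) {
      best <- model
      best_loss <- final
    }
    if (best_loss < loss_target) break
  }
  best
}

train_agtm_once <- function(dataset, config, layout, seed, verbose) {
  set.seed(as.integer(seed))
  mats <- lapply(dataset$sequences, seq_to_norm_mat, layout = layout,
                 velocity = config$clf_velocity)
  C_in <- ncol(mats[[1L]])
  J <- layout$n_joints
  params <- agtm_params(C_in, config)
  A0 <- build_static_adjacency(layout)
  lambda <- config$adjacency_lambda
  opt <- adam_state(params)
  lr <- config$clf_lr
  hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (ep in seq_len(config$clf_epochs)) {
    if (ep %in% config$clf_milestones) lr <- lr * config$clf_gamma
    idx <- sample.int(length(mats))
    ep_loss <- 0
    for (i in idx) {
      xin <- mats[[i]]
      if (config$clf_augment) {
        # Augmentation happens at the coordinate level, before velocity
        # channels: random planar rotation, per-joint constant offsets
        # (resting-posture invariance) and coordinate jitter; velocity
        # channels are then recomputed from the augmented positions so
        # they stay physically consistent. Rotation and offsets leave the
        # class-bearing motion amplitude untouched.
        C0 <- if (config$clf_velocity) ncol(xin) %/% 2L else ncol(xin)
        pos <- xin[, seq_len(C0), drop = FALSE]
        Ti <- nrow(pos) %/% J
        # random contiguous temporal crop (75-100% of the frames) and
        # random time reversal; both preserve per-joint motion amplitude
        keep <- sample(ceiling(0.75 * Ti):Ti, 1L)
        start <- sample.int(Ti - keep + 1L, 1L)
        tidx <- start:(start + keep - 1L)
        if (stats::runif(1) < 0.5) tidx <- rev(tidx)
        rows <- as.vector(outer(seq_len(J), (tidx - 1L) * J, `+`))
        pos <- pos[rows, , drop = FALSE]
        th <- stats::runif(1, 0, 2 * pi)
        R <- diag(C0)
        R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        off <- matrix(stats::rnorm(J * C0, 0, 2 * config$clf_jitter_sd), J, C0)
        pos <- pos %*% R + off[rep(seq_len(J), nrow(pos) %/% J), ] +
          matrix(stats::rnorm(length(pos), 0, config$clf_jitter_sd),
                 nrow(pos), C0)
        if (config$clf_velocity) {
          vel <- pos * 0
          vel[-seq_len(J), ] <- pos[-seq_len(J), , drop = FALSE] -
            pos[seq_len(nrow(pos) - J), , drop = FALSE]
          xin <- cbind(pos, vel)
        } else {
          xin <- pos
        }
      }
      tape <- ag_tape()
      wp <- ag_wrap_params(tape, params)
      z <- agtm_logit(tape, wp, ag_leaf(tape, xin), nrow(xin) %/% J, J, A0,
                      lambda, config)
      loss <- ag_bce_logit(tape, z, dataset$labels[i])
      ag_backward(tape, loss)
      if (!is.finite(loss$value[1L])) stop("non-finite loss at epoch ", ep)
      if (lr > 0) {
        st <- adam_step(params, clip_grads(ag_collect_grads(wp),
                                           config$grad_clip), opt, lr)
        params <- st$params
        opt <- st$state
      }
      ep_loss <- ep_loss + loss$value[1L]
    }
    ep_loss <- ep_loss / length(mats)
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  lr %.6f", ep, ep_loss, lr))
    }
  }
  structure(list(params = params, config = config, layout = layout,
                 input_channels = C_in, A0 = A0, lambda = lambda,
                 task_name = dataset$task_name, history = hist),
            class = "agtm_model")
}

# logit for one sequence (or pre-normalised matrix) under a trained model
agtm_score <- function(model, s, as_matrix = FALSE) {
  mat <- if (as_matrix) s else
    seq_to_norm_mat(s, model$layout, velocity = model$config$clf_velocity)
  J <- model$layout$n_joints
  tape <- ag_tape()
  wp <- ag_wrap_params(tape, model$params)
  z <- agtm_logit(tape, wp, ag_leaf(tape, mat), nrow(mat) %/% J, J,
                  model$A0, model$lambda, model$config)
  z$value[1L]
}

#' Predict class probabilities with a trained classifier
#'
#' @param model an `agtm_model`.
#' @param sequences list of sequences (or a `labeled_dataset`).
#' @return data frame with columns `prob` (probability of class 1) and
#'   `label` (0/1 prediction; ties at 0.5 go to class 1).
#' @export
predict_agtm <- function(model, sequences) {
  if (inherits(sequences, "labeled_dataset")) sequences <- sequences$sequences
  probs <- vapply(sequences, function(s) {
    1 / (1 + exp(-agtm_score(model, s)))
  }, numeric(1))
  data.frame(prob = probs, label = as.integer(probs >= 0.5))
}

#' Binary classification metrics
#'
#' Confusion counts and accuracy/precision/recall/F1. Undefined ratios
#' (zero denominators) are reported as 0 and flagged in `degenerate`
#' rather than returned as `NaN`.
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels.
#' @return an object of class `classification_report`.
#' @export
classification_metrics <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions)) stop("length mismatch")
  if (!all(c(labels, predictions) %in% c(0L, 1L))) stop("labels must be binary")
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  tn <- sum(labels == 0L & predictions == 0L)
  degenerate <- character(0)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else {
    degenerate <- c(degenerate, "precision"); 0
  }
  recall <- if (tp + fn > 0L) tp / (tp + fn) else {
    degenerate <- c(degenerate, "recall"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    degenerate <- c(degenerate, "f1"); 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> acc %.3f | prec %.3f | ",
                     "rec %.3f | F1 %.3f (TP %d FP %d FN %d TN %d)\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  if (length(x$degenerate)) {
    cat("  degenerate: ", paste(x$degenerate, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.agtm_model <- function(x, ...) {
  cat("<agtm_model> ", x$config$gcn_layers, " graph layers, C'=",
      x$config$gcn_dim, ", lambda=", x$lambda, ", task=", x$task_name,
      "\n", sep = "")
  invisible(x)
}
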