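# Building blocks of the dual-stage pose lifter.
#
# Each exported operation runs the same autodiff code path the trained model
# uses (on a throwaway tape), so the algebra tested here is the algebra that
# is optimised. Weight containers are plain named lists of matrices; a NULL
# weights argument means zero-initialised output paths, under which every
# residual block is the exact identity.

# --- weight constructors -----------------------------------------------------

rmat <- function(nr, nc, zero = FALSE) {
  if (zero) matrix(0, nr, nc) else
    matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

ffn_weights <- function(d, hidden, zero = FALSE) {
  list(ln_g = matrix(1, 1, d), ln_b = matrix(0, 1, d),
       W1 = rmat(d, hidden, zero), b1 = matrix(0, 1, hidden),
       W2 = rmat(hidden, d, zero), b2 = matrix(0, 1, d))
}

conv_weights <- function(d_in, d_out, kernel, zero = FALSE) {
  list(W = lapply(seq_len(kernel), function(i) rmat(d_in, d_out, zero)),
       b = matrix(0, 1, d_out))
}

block_weights <- function(d, hidden, zero = FALSE) {
  list(ln1_g = matrix(1, 1, d), ln1_b = matrix(0, 1, d),
       Wq = rmat(d, d, zero), Wk = rmat(d, d, zero),
       Wv = rmat(d, d, zero), Wo = rmat(d, d, zero), bo = matrix(0, 1, d),
       ln2_g = matrix(1, 1, d), ln2_b = matrix(0, 1, d),
       Wm1 = rmat(d, hidden, zero), bm1 = matrix(0, 1, hidden),
       Wm2 = rmat(hidden, d, zero), bm2 = matrix(0, 1, d))
}

asw_head_weights <- function(d, hidden, zero = FALSE) {
  list(W1 = rmat(d, hidden, zero), b1 = matrix(0, 1, hidden),
       W2 = rmat(hidden, 1, zero), b2 = matrix(0, 1, 1))
}

linear_weights <- function(d_in, d_out, zero = FALSE) {
  list(W = rmat(d_in, d_out, zero), b = matrix(0, 1, d_out))
}

# --- autodiff block forwards -------------------------------------------------

ag_linear <- function(tape, x, p) {
  ag_add(tape, ag_matmul(tape, x, p$W), p$b)
}

# Z = X + FFN(LayerNorm(X))
ag_ffn_block <- function(tape, x, p) {
  h <- ag_layernorm_rows(tape, x, p$ln_g, p$ln_b)
  h <- ag_relu(tape, ag_add(tape, ag_matmul(tape, h, p$W1), p$b1))
  h <- ag_add(tape, ag_matmul(tape, h, p$W2), p$b2)
  ag_add(tape, x, h)
}

# temporal 1-d convolution with same padding, expressed as shifted matmuls
ag_conv1d <- function(tape, x, p) {
  K <- length(p$W)
  if (K > nrow(x$value)) stop("kernel longer than sequence")
  half <- (K - 1L) %/% 2L
  acc <- NULL
  for (i in seq_len(K)) {
    offset <- i - 1L - half                      # tap at x[t + offset]
    term <- ag_matmul(tape, ag_shift_rows(tape, x, -offset), p$W[[i]])
    acc <- if (is.null(acc)) term else ag_add(tape, acc, term)
  }
  ag_add(tape, acc, p$b)
}

# multi-head self/cross attention; q_in supplies queries, kv_in keys+values
ag_mha <- function(tape, q_in, kv_in, p, heads) {
  d <- ncol(q_in$value)
  if (d %% heads != 0L) stop("feature dim not divisible by head count")
  dh <- d %/% heads
  q <- ag_matmul(tape, q_in, p$Wq)
  k <- ag_matmul(tape, kv_in, p$Wk)
  v <- ag_matmul(tape, kv_in, p$Wv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- ag_cols(tape, q, cols)
    kh <- ag_cols(tape, k, cols)
    vh <- ag_cols(tape, v, cols)
    a <- ag_softmax_rows(tape, ag_scale(tape, ag_matmul(tape, qh, ag_t(tape, kh)),
                                        1 / sqrt(dh)))
    outs[[h]] <- ag_matmul(tape, a, vh)
  }
  cat_ <- if (heads == 1L) outs[[1L]] else ag_cbind(tape, outs)
  ag_add(tape, ag_matmul(tape, cat_, p$Wo), p$bo)
}

# pre-norm transformer block: X + MLP(LN2(X + Attn(LN1(X))))
ag_xformer_block <- function(tape, x, p, heads) {
  a <- ag_mha(tape, ag_layernorm_rows(tape, x, p$ln1_g, p$ln1_b),
              ag_layernorm_rows(tape, x, p$ln1_g, p$ln1_b), p, heads)
  inner <- ag_add(tape, x, a)
  h <- ag_layernorm_rows(tape, inner, p$ln2_g, p$ln2_b)
  h <- ag_relu(tape, ag_add(tape, ag_matmul(tape, h, p$Wm1), p$bm1))
  h <- ag_add(tape, ag_matmul(tape, h, p$Wm2), p$bm2)
  ag_add(tape, x, h)
}

# parameter-free cross-attention fusion: Softmax(E1 E2^T / sqrt(d)) E2
ag_cross_attention <- function(tape, e1, e2) {
  d <- ncol(e1$value)
  if (ncol(e2$value) != d) stop("dim mismatch between attention streams")
  a <- ag_softmax_rows(tape, ag_scale(tape, ag_matmul(tape, e1, ag_t(tape, e2)),
                                      1 / sqrt(d)))
  list(fused = ag_matmul(tape, a, e2), attention = a)
}

# per-scale sigmoid gate from time-pooled features
ag_asw_alpha <- function(tape, x, p) {
  g <- ag_colmeans(tape, x)
  h <- ag_relu(tape, ag_add(tape, ag_matmul(tape, g, p$W1), p$b1))
  z <- ag_add(tape, ag_matmul(tape, h, p$W2), p$b2)
  ag_sigmoid(tape, z)
}

ag_cols <- function(tape, a, idx) {
  av <- a$value
  ag_node(tape, av[, idx, drop = FALSE], function(g) {
    g0 <- matrix(0, nrow(av), ncol(av))
    g0[, idx] <- g
    ag_acc(a, g0)
  })
}

# --- exported operation surface ---------------------------------------------

run_plain <- function(fn) {
  tape <- ag_tape()
  fn(tape)$value
}

#' Residual feed-forward encoding block
#'
#' Computes `Z = X + FFN(LayerNorm(X))`. With `weights = NULL` every weight
#' is zero, the feed-forward branch vanishes, and the block is the exact
#' identity.
#'
#' @param X numeric matrix, frames x features.
#' @param weights list as produced internally (`ln_g`, `ln_b`, `W1`, `b1`,
#'   `W2`, `b2`), or `NULL` for the zero-initialised block.
#' @return matrix of the same shape as `X`.
#' @export
residual_block <- function(X, weights = NULL) {
  X <- as_mat(X)
  if (anyNA(X)) stop("NaN input")
  if (is.null(weights)) weights <- ffn_weights(ncol(X), ncol(X), zero = TRUE)
  run_plain(function(tape) {
    ag_ffn_block(tape, ag_leaf(tape, X), ag_wrap_params(tape, weights))
  })
}

#' Temporal 1-d convolution projection
#'
#' Maps the channel dimension through a one-dimensional convolution along
#' the time axis with same padding (output length equals input length).
#'
#' @param Z input matrix, frames x channels.
#' @param weights list with `W` (list of kernel-tap matrices, ordered from
#'   the earliest tap) and `b` (bias row); `NULL` gives a kernel-1 identity
#'   when channel counts match.
#' @return matrix frames x output-channels.
#' @export
project_stream <- function(Z, weights = NULL) {
  Z <- as_mat(Z)
  if (is.null(weights)) weights <- list(W = list(diag(ncol(Z))),
                                        b = matrix(0, 1, ncol(Z)))
  run_plain(function(tape) {
    ag_conv1d(tape, ag_leaf(tape, Z), ag_wrap_params(tape, weights))
  })
}

#' Cross-attention fusion of two feature streams
#'
#' `Softmax(E1 E2^T / sqrt(d)) E2`, with `E1` as query and `E2` as key and
#' value. Attention rows are probability vectors, so every output row is a
#' convex combination of the rows of `E2`.
#'
#' @param E1,E2 matrices with equal token count and feature dimension.
#' @param return_attention also return the attention matrix.
#' @return the fused matrix, or a list `(fused, attention)` when
#'   `return_attention` is `TRUE`.
#' @export
cross_attention_fuse <- function(E1, E2, return_attention = FALSE) {
  E1 <- as_mat(E1); E2 <- as_mat(E2)
  tape <- ag_tape()
  res <- ag_cross_attention(tape, ag_leaf(tape, E1), ag_leaf(tape, E2))
  if (return_attention) {
    list(fused = res$fused$value, attention = res$attention$value)
  } else {
    res$fused$value
  }
}

#' Crop padded tokens back to the original length
#'
#' @param X matrix with `F + 2P` rows.
#' @param P pad count; `P = 0` is the identity.
#' @return the central `F` rows.
#' @export
crop_to_original <- function(X, P) {
  X <- as_mat(X)
  P <- as.integer(P)
  if (P < 0L) stop("P must be >= 0")
  if (nrow(X) < 2L * P + 1L) stop("token count must exceed 2P")
  if (P == 0L) return(X)
  X[(P + 1L):(nrow(X) - P), , drop = FALSE]
}

#' Split a feature sequence into equal temporal segments
#'
#' @param X matrix with F rows; F must be divisible by `s_d`.
#' @param s_d segment length.
#' @return list of `F / s_d` matrices; segment i holds frames
#'   `(i-1)*s_d + 1 .. i*s_d` in order.
#' @export
temporal_segment <- function(X, s_d) {
  X <- as_mat(X)
  s_d <- as.integer(s_d)
  F_ <- nrow(X)
  if (s_d < 1L || F_ %% s_d != 0L) {
    stop("sequence length must be divisible by the segment length")
  }
  lapply(seq_len(F_ %/% s_d), function(i) {
    X[((i - 1L) * s_d + 1L):(i * s_d), , drop = FALSE]
  })
}

#' Recompose temporal segments into a continuous sequence
#'
#' Exact inverse of [temporal_segment()].
#'
#' @param segments list of matrices.
#' @return the row-bound matrix.
#' @export
inverse_recompose <- function(segments) {
  if (!length(segments)) stop("empty segment list")
  do.call(rbind, segments)
}

#' Spatial transformer encoding block
#'
#' Pre-norm block `X + MLP(LN(X + Attn(LN(X))))` with multi-head
#' self-attention. `weights = NULL` zero-initialises the attention and MLP
#' output paths, which makes the block the exact identity.
#'
#' @param X matrix, tokens x features.
#' @param weights block weight list or `NULL`.
#' @param heads attention head count (must divide the feature dim).
#' @return matrix of the same shape.
#' @export
spatial_encode <- function(X, weights = NULL, heads = 1L) {
  X <- as_mat(X)
  if (anyNA(X)) stop("NaN input")
  if (is.null(weights)) weights <- block_weights(ncol(X), ncol(X), zero = TRUE)
  run_plain(function(tape) {
    ag_xformer_block(tape, ag_leaf(tape, X), ag_wrap_params(tape, weights), heads)
  })
}

#' Local temporal encoding of segments
#'
#' Applies a shared-weight pre-norm transformer block independently inside
#' each segment: attention never mixes information across segments, so
#' perturbing one segment leaves all other segments' outputs unchanged.
#'
#' @param segments list of matrices from [temporal_segment()].
#' @param weights shared block weight list or `NULL` (identity).
#' @param heads attention head count.
#' @return list of encoded segments.
#' @export
local_temporal_encode <- function(segments, weights = NULL, heads = 1L) {
  if (!length(segments)) stop("empty segment list")
  if (is.null(weights)) {
    weights <- block_weights(ncol(segments[[1L]]), ncol(segments[[1L]]),
                             zero = TRUE)
  }
  lapply(segments, function(s) spatial_encode(s, weights, heads))
}

#' Adaptive scale weights
#'
#' For every scale output, pools features over time (global average
#' pooling), passes the pooled vector through a small two-layer MLP and a
#' sigmoid. Each weight lies in (0, 1) and depends only on its own scale's
#' features. `weights = NULL` uses zero MLPs, giving 0.5 for every scale.
#'
#' @param scale_outputs list of D matrices (frames x features).
#' @param weights list of D per-scale MLP weight lists, or `NULL`.
#' @return numeric vector of D weights in (0, 1).
#' @export
asw_weights <- function(scale_outputs, weights = NULL) {
  if (!length(scale_outputs)) stop("empty scale list")
  D <- length(scale_outputs)
  if (is.null(weights)) {
    weights <- lapply(scale_outputs, function(s) {
      asw_head_weights(ncol(s), max(1L, ncol(s) %/% 4L), zero = TRUE)
    })
  }
  vapply(seq_len(D), function(d) {
    run_plain(function(tape) {
      ag_asw_alpha(tape, ag_leaf(tape, as_mat(scale_outputs[[d]])),
                   ag_wrap_params(tape, weights[[d]]))
    })[1L]
  }, numeric(1))
}

#' Weighted multi-scale fusion
#'
#' Elementwise weighted sum `sum_d alpha_d * X_d` with no renormalization
#' (the weights are independent sigmoid gates, not a softmax).
#'
#' @param scale_outputs list of D equally shaped matrices.
#' @param alpha numeric vector of D weights.
#' @return the fused matrix.
#' @export
asw_fuse <- function(scale_outputs, alpha) {
  if (length(scale_outputs) != length(alpha)) stop("one weight per scale required")
  dims <- lapply(scale_outputs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]]))) {
    stop("shape mismatch across scales")
  }
  Reduce(`+`, Map(function(s, a) a * s, scale_outputs, alpha))
}

#' Regression head mapping fused features to 3D poses
#'
#' A frame-wise linear map (1x1 convolution) from the fused feature vector
#' to `J * 3` coordinates, reshaped to an F x J x 3 pose array.
#'
#' @param F_multi matrix, F x features.
#' @param weights list with `W` (features x 3J) and `b`; `NULL` gives the
#'   all-zero pose for `J` joints.
#' @param J joint count.
#' @return a `pose_sequence_3d`.
#' @export
regress_head <- function(F_multi, weights = NULL, J) {
  F_multi <- as_mat(F_multi)
  if (is.null(weights)) weights <- linear_weights(ncol(F_multi), 3L * J, zero = TRUE)
  if (ncol(weights$W) != 3L * J) stop("feature dim not mappable to J*3")
  out <- run_plain(function(tape) {
    ag_linear(tape, ag_leaf(tape, F_multi), ag_wrap_params(tape, weights))
  })
  pose_sequence_3d(unflatten_coords(out, J, 3L))
}
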