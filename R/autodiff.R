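# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). Nodes are
# environments holding $value and $grad; operation nodes carry a $backward
# closure that accumulates gradients into their parents. The tape records
# creation order, and ag_backward() replays it in reverse. This is all the
# machinery the pose-lifting and graph-classifier networks need; it is not a
# general tensor framework.

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

#' Create a fresh autodiff tape
#'
#' A tape records every node created against it, in order, so that
#' [ag_backward()] can replay the computation in reverse and accumulate
#' gradients. One tape is used per forward/backward pass.
#'
#' @return An environment with the internal tape state.
#' @keywords internal
#' @export
ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$last <- NULL
  e
}

# O(1) append: the tape is a linked list threaded through the nodes
ag_push <- function(tape, nd) {
  nd$prev <- tape$last
  tape$last <- nd
  nd
}

#' Create a leaf node on a tape
#'
#' @param tape tape from [ag_tape()]
#' @param value numeric matrix (or vector, promoted to a 1-row matrix)
#' @return a node whose `$grad` is populated after [ag_backward()]
#' @keywords internal
#' @export
ag_leaf <- function(tape, value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- as_mat(value)
  nd$grad <- NULL
  nd$backward <- NULL
  ag_push(tape, nd)
}

ag_node <- function(tape, value, backward) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  ag_push(tape, nd)
}

ag_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

#' Run backpropagation from a (scalar or tensor) node
#'
#' Seeds the node's gradient with ones and replays the tape in reverse.
#'
#' @param tape the tape the graph was built on
#' @param node node to differentiate; usually a 1x1 loss
#' @keywords internal
#' @export
ag_backward <- function(tape, node) {
  node$grad <- matrix(1, nrow(node$value), ncol(node$value))
  cur <- tape$last
  while (!is.null(cur)) {
    if (!is.null(cur$grad) && !is.null(cur$backward)) cur$backward(cur$grad)
    cur <- cur$prev
  }
  invisible(node)
}

# --- elementwise / broadcasting ---------------------------------------------

# b may have the same shape as a, be a 1x1 scalar, or a single row (bias).
ag_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (all(dim(av) == dim(bv))) {
    ag_node(tape, av + bv, function(g) { ag_acc(a, g); ag_acc(b, g) })
  } else if (nrow(bv) == 1L && ncol(bv) == 1L) {
    ag_node(tape, av + bv[1L], function(g) {
      ag_acc(a, g); ag_acc(b, matrix(sum(g), 1L, 1L))
    })
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    ag_node(tape, sweep(av, 2L, as.numeric(bv), "+"), function(g) {
      ag_acc(a, g); ag_acc(b, matrix(colSums(g), 1L))
    })
  } else {
    stop("ag_add: incompatible shapes")
  }
}

ag_sub <- function(tape, a, b) ag_add(tape, a, ag_scale(tape, b, -1))

# elementwise product; b may be 1x1 (scalar gate, e.g. a scale weight)
ag_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (all(dim(av) == dim(bv))) {
    ag_node(tape, av * bv, function(g) {
      ag_acc(a, g * bv); ag_acc(b, g * av)
    })
  } else if (nrow(bv) == 1L && ncol(bv) == 1L) {
    ag_node(tape, av * bv[1L], function(g) {
      ag_acc(a, g * bv[1L]); ag_acc(b, matrix(sum(g * av), 1L, 1L))
    })
  } else {
    stop("ag_mul: incompatible shapes")
  }
}

ag_scale <- function(tape, a, k) {
  ag_node(tape, a$value * k, function(g) ag_acc(a, g * k))
}

# add a constant matrix (no gradient flows into the constant)
ag_addc <- function(tape, a, const) {
  ag_node(tape, a$value + const, function(g) ag_acc(a, g))
}

ag_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ag_node(tape, av %*% bv, function(g) {
    ag_acc(a, g %*% t(bv)); ag_acc(b, t(av) %*% g)
  })
}

ag_t <- function(tape, a) {
  ag_node(tape, t(a$value), function(g) ag_acc(a, t(g)))
}

ag_relu <- function(tape, a) {
  av <- a$value
  ag_node(tape, pmax(av, 0), function(g) ag_acc(a, g * (av > 0)))
}

# logits are clamped well inside the exp() range: values beyond +-500 are
# saturated anyway, and letting exp() underflow into subnormal doubles makes
# every subsequent arithmetic op orders of magnitude slower on x86
ag_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-pmin(pmax(a$value, -500), 500)))
  ag_node(tape, y, function(g) ag_acc(a, g * y * (1 - y)))
}

# --- row-structured ops ------------------------------------------------------

ag_softmax_rows <- function(tape, a) {
  av <- a$value
  e <- exp(pmax(av - apply(av, 1L, max), -500))
  y <- e / rowSums(e)
  ag_node(tape, y, function(g) {
    ag_acc(a, y * (g - rowSums(g * y)))
  })
}

# LayerNorm over the column (feature) direction of each row; gamma/beta 1xC
ag_layernorm_rows <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value); bv <- as.numeric(beta$value)
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_node(tape, y, function(g) {
    ag_acc(gamma, matrix(colSums(g * xhat), 1L))
    ag_acc(beta, matrix(colSums(g), 1L))
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    ag_acc(x, dx)
  })
}

ag_rows <- function(tape, a, idx) {
  av <- a$value
  ag_node(tape, av[idx, , drop = FALSE], function(g) {
    g0 <- matrix(0, nrow(av), ncol(av))
    if (anyDuplicated(idx)) {
      agg <- rowsum(g, group = idx)           # accumulate repeated rows
      g0[as.integer(rownames(agg)), ] <- agg
    } else {
      g0[idx, ] <- g
    }
    ag_acc(a, g0)
  })
}

ag_rbind <- function(tape, lst) {
  sizes <- vapply(lst, function(nd) nrow(nd$value), integer(1))
  ag_node(tape, do.call(rbind, lapply(lst, function(nd) nd$value)), function(g) {
    off <- 0L
    for (i in seq_along(lst)) {
      ag_acc(lst[[i]], g[(off + 1L):(off + sizes[i]), , drop = FALSE])
      off <- off + sizes[i]
    }
  })
}

ag_cbind <- function(tape, lst) {
  sizes <- vapply(lst, function(nd) ncol(nd$value), integer(1))
  ag_node(tape, do.call(cbind, lapply(lst, function(nd) nd$value)), function(g) {
    off <- 0L
    for (i in seq_along(lst)) {
      ag_acc(lst[[i]], g[, (off + 1L):(off + sizes[i]), drop = FALSE])
      off <- off + sizes[i]
    }
  })
}

# shift rows by s (s > 0 pushes rows towards larger indices), zero-filled;
# used to express a 1-d temporal convolution as a sum of shifted matmuls
ag_shift_rows <- function(tape, a, s) {
  av <- a$value
  n <- nrow(av)
  y <- matrix(0, n, ncol(av))
  if (s == 0L) {
    y <- av
  } else if (s > 0L && s < n) {
    y[(s + 1L):n, ] <- av[1L:(n - s), ]
  } else if (s < 0L && -s < n) {
    y[1L:(n + s), ] <- av[(1L - s):n, ]
  }
  ag_node(tape, y, function(g) {
    g0 <- matrix(0, n, ncol(av))
    if (s == 0L) {
      g0 <- g
    } else if (s > 0L && s < n) {
      g0[1L:(n - s), ] <- g[(s + 1L):n, ]
    } else if (s < 0L && -s < n) {
      g0[(1L - s):n, ] <- g[1L:(n + s), ]
    }
    ag_acc(a, g0)
  })
}

ag_colmeans <- function(tape, a) {
  av <- a$value
  nr <- nrow(av)
  ag_node(tape, matrix(colMeans(av), 1L), function(g) {
    ag_acc(a, matrix(as.numeric(g), nr, ncol(av), byrow = TRUE) / nr)
  })
}

ag_mean <- function(tape, a) {
  av <- a$value
  ag_node(tape, matrix(mean(av), 1L, 1L), function(g) {
    ag_acc(a, matrix(g[1L] / length(av), nrow(av), ncol(av)))
  })
}

ag_sum <- function(tape, a) {
  av <- a$value
  ag_node(tape, matrix(sum(av), 1L, 1L), function(g) {
    ag_acc(a, matrix(g[1L], nrow(av), ncol(av)))
  })
}

# --- losses ------------------------------------------------------------------

# Mean per-joint Euclidean distance between a predicted F x (J*C) matrix and a
# constant truth matrix with joint-major column grouping. Matches the MPJPE
# evaluation metric, so training minimises the quantity that is reported.
ag_pose_l2 <- function(tape, pred, truth, J) {
  pv <- pred$value
  C <- ncol(pv) / J
  stopifnot(C == round(C))
  D <- pv - truth
  jidx <- rep(seq_len(J), each = C)
  d2 <- t(rowsum(t(D^2), group = jidx))       # F x J squared distances
  dmat <- sqrt(d2)
  val <- mean(dmat)
  ag_node(tape, matrix(val, 1L, 1L), function(g) {
    dexp <- dmat[, jidx, drop = FALSE]
    grad <- ifelse(dexp > 0, D / pmax(dexp, .Machine$double.xmin), 0)
    ag_acc(pred, grad * (g[1L] / length(dmat)))
  })
}

# numerically stable binary cross-entropy on a 1x1 logit node
ag_bce_logit <- function(tape, z, y) {
  zv <- z$value[1L]
  val <- max(zv, 0) - zv * y + log1p(exp(-abs(zv)))
  ag_node(tape, matrix(val, 1L, 1L), function(g) {
    p <- 1 / (1 + exp(-zv))
    ag_acc(z, matrix((p - y) * g[1L], 1L, 1L))
  })
}

# --- parameter plumbing ------------------------------------------------------

# wrap a named (possibly nested) list of matrices as leaves on a tape
ag_wrap_params <- function(tape, params) {
  rapply(params, function(v) ag_leaf(tape, v), classes = "ANY", how = "replace")
}

# collect gradients from wrapped parameters, zeros where untouched
ag_collect_grads <- function(wrapped) {
  rapply(wrapped, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
  }, classes = "ANY", how = "replace")
}

# --- Adam optimiser ----------------------------------------------------------

adam_state <- function(params) {
  list(
    m = rapply(params, function(v) v * 0, classes = "ANY", how = "replace"),
    v = rapply(params, function(v) v * 0, classes = "ANY", how = "replace"),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  flat_p <- unlist_mats(params)
  flat_g <- unlist_mats(grads)
  flat_m <- unlist_mats(state$m)
  flat_v <- unlist_mats(state$v)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat_p)) {
    gk <- flat_g[[k]]
    gk[abs(gk) < 1e-30] <- 0        # flush subnormal-range gradients
    flat_m[[k]] <- beta1 * flat_m[[k]] + (1 - beta1) * gk
    flat_v[[k]] <- beta2 * flat_v[[k]] + (1 - beta2) * gk^2
    mhat <- flat_m[[k]] / bc1
    vhat <- flat_v[[k]] / bc2
    flat_p[[k]] <- flat_p[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(
    params = relist_mats(flat_p, params),
    state = list(m = relist_mats(flat_m, params),
                 v = relist_mats(flat_v, params),
                 t = state$t)
  )
}

# clip gradients to a maximum global L2 norm (standard training stabiliser)
clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  flat <- unlist_mats(grads)
  total <- sqrt(sum(vapply(flat, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    k <- max_norm / total
    flat <- lapply(flat, function(g) g * k)
    grads <- relist_mats(flat, grads)
  }
  grads
}

# stable per-element keys for nested parameter lists; unnamed elements
# (e.g. convolution taps) fall back to their position
elem_keys <- function(x) {
  nms <- names(x)
  if (is.null(nms)) nms <- rep("", length(x))
  ifelse(nzchar(nms), nms, paste0("..", seq_along(x)))
}

# flatten a nested list of matrices into a single named list
unlist_mats <- function(x, prefix = "") {
  out <- list()
  keys <- elem_keys(x)
  for (i in seq_along(x)) {
    key <- paste0(prefix, keys[i])
    if (is.list(x[[i]])) {
      out <- c(out, unlist_mats(x[[i]], paste0(key, ".")))
    } else {
      out[[key]] <- x[[i]]
    }
  }
  out
}

relist_mats <- function(flat, skeleton, prefix = "") {
  out <- skeleton
  keys <- elem_keys(skeleton)
  for (i in seq_along(skeleton)) {
    key <- paste0(prefix, keys[i])
    if (is.list(skeleton[[i]])) {
      out[[i]] <- relist_mats(flat, skeleton[[i]], paste0(key, "."))
    } else {
      out[[i]] <- flat[[key]]
    }
  }
  out
}
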