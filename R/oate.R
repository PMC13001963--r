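# Occlusion-aware and trend-enhanced input stage.
#
# TLSI (temporal locally smoothed interpolation) replaces each missing joint
# with a confidence- and distance-weighted mean of the same joint's observed
# positions in neighbouring frames:
#   p_{f,j} = sum_{f' in N(f)} w(f,f') p_{f',j} / sum w(f,f'),
#   w(f,f') = exp(-lambda_t |f - f'|) * c_{f',j}.
# TTEP (temporal trend extrapolated padding) synthesises P boundary frames
# on each side from the mean consecutive-frame difference of the first/last
# k frames, so that padded frames continue the local motion trend instead of
# duplicating the boundary frame.

#' TLSI interpolation weight
#'
#' Computes `exp(-lambda_t * |f - f_prime|) * c`: strictly decreasing in the
#' temporal distance when `lambda_t > 0`, and linear in the confidence.
#'
#' @param f frame index of the missing entry.
#' @param f_prime neighbouring frame index.
#' @param c confidence of the neighbour, in `[0, 1]`.
#' @param lambda_t time-decay factor, `>= 0`.
#' @return a nonnegative weight.
#' @examples
#' tlsi_weight(10, 9, 0.8, 0.5) # 0.8 * exp(-0.5)
#' @export
tlsi_weight <- function(f, f_prime, c, lambda_t) {
  if (any(lambda_t < 0)) stop("lambda_t must be >= 0")
  if (any(c < 0 | c > 1)) stop("confidence must lie in [0, 1]")
  exp(-lambda_t * abs(f - f_prime)) * c
}

#' Impute missing joints by temporal locally smoothed interpolation
#'
#' Observed entries are untouched. Each missing `(frame, joint)` entry is
#' replaced by the normalized weighted mean of the same joint's observed
#' positions within `window_halfwidth` frames on each side; if no observed
#' neighbour exists there (or all neighbour weights are exactly zero), the
#' window widens to the whole sequence. A joint observed nowhere cannot be
#' interpolated and raises an error. Imputed points are convex combinations
#' of their neighbours, so they always lie inside the neighbours' bounding
#' box.
#'
#' @param seq a `pose_sequence_2d`.
#' @param window_halfwidth frames searched on each side (>= 1).
#' @param lambda_t time-decay factor (>= 0).
#' @return a `pose_sequence_2d` with `observed` all `TRUE`.
#' @export
tlsi_impute <- function(seq, window_halfwidth = 5L, lambda_t = 0.5) {
  stopifnot(inherits(seq, "pose_sequence_2d"))
  window_halfwidth <- as.integer(window_halfwidth)
  if (window_halfwidth < 1L) stop("window_halfwidth must be >= 1")
  if (lambda_t < 0) stop("lambda_t must be >= 0")
  coords <- seq$coords
  conf <- seq$confidence
  obs <- seq$observed
  F_ <- seq$n_frames
  for (j in seq_len(seq$n_joints)) {
    miss <- which(!obs[, j])
    if (!length(miss)) next
    ok <- which(obs[, j])
    if (!length(ok)) {
      stop("uninterpolatable joint: joint ", j, " is never observed")
    }
    for (f in miss) {
      nb <- ok[abs(ok - f) <= window_halfwidth]
      w <- tlsi_weight(f, nb, conf[nb, j], lambda_t)
      if (!length(nb) || sum(w) == 0) {   # fallback: widen to full sequence
        nb <- ok
        w <- tlsi_weight(f, nb, conf[nb, j], lambda_t)
      }
      if (sum(w) == 0) {
        stop("uninterpolatable joint: joint ", j,
             " has zero total weight everywhere")
      }
      coords[f, j, ] <- colSums(coords[nb, j, , drop = FALSE] * w) / sum(w)
    }
    conf[miss, j] <- 0
    obs[miss, j] <- TRUE
  }
  # observed entries keep their confidence; imputed entries get the neutral
  # confidence 1 so later stages treat them as filled
  newconf <- seq$confidence
  newconf[!seq$observed] <- 1
  pose_sequence_2d(coords, newconf, obs)
}

#' Mean consecutive-frame difference over a boundary window
#'
#' For k boundary frames, returns the mean of the k - 1 consecutive
#' differences, which telescopes to `(X_k - X_1) / (k - 1)`.
#'
#' @param boundary_frames k x J x C array (or k x M matrix) of frames.
#' @return the trend: a J x C matrix (or length-M vector for matrix input).
#' @export
ttep_trend <- function(boundary_frames) {
  if (is.matrix(boundary_frames)) {
    k <- nrow(boundary_frames)
    if (k < 2L) stop("trend window must contain at least 2 frames")
    return(colMeans(boundary_frames[-1L, , drop = FALSE] -
                      boundary_frames[-k, , drop = FALSE]))
  }
  stopifnot(is.array(boundary_frames), length(dim(boundary_frames)) == 3L)
  k <- dim(boundary_frames)[1]
  if (k < 2L) stop("trend window must contain at least 2 frames")
  diffs <- boundary_frames[-1L, , , drop = FALSE] -
    boundary_frames[-k, , , drop = FALSE]
  apply(diffs, c(2, 3), mean)
}

#' Trend-extrapolated boundary padding
#'
#' Prepends and appends `P` synthetic frames. Tail pads follow
#' `X_{F+p} = X_F + p * Delta_tail`. Head pads depend on `head_mode`:
#' `"continuity"` (default) uses `X_{1-p} = X_1 - p * Delta_head`, so the
#' padded sequence continues the head trend backwards and an exactly linear
#' sequence stays exactly linear; `"as_printed"` uses
#' `X_{-p} = X_1 + p * Delta_head`, the literal published formula, which
#' mirrors the start of the sequence forward instead of extrapolating it.
#'
#' @param seq a `pose_sequence_2d`, `pose_sequence_3d`, or an F x J x C
#'   array.
#' @param k trend window (>= 2); requires `F >= k` when `P > 0`.
#' @param P pad count per side (>= 0).
#' @param head_mode `"continuity"` or `"as_printed"`.
#' @return a `padded_sequence`.
#' @export
ttep_pad <- function(seq, k = 3L, P = 5L,
                     head_mode = c("continuity", "as_printed")) {
  head_mode <- match.arg(head_mode)
  coords <- if (is.array(seq) && length(dim(seq)) == 3L) seq else seq$coords
  k <- as.integer(k); P <- as.integer(P)
  if (k < 2L) stop("k must be >= 2")
  if (P < 0L) stop("P must be >= 0")
  F_ <- dim(coords)[1]
  if (P > 0L && F_ < k) stop("padding requires F >= k")
  if (P == 0L) return(padded_sequence(coords, F_, 0L))
  d_head <- ttep_trend(coords[1:k, , , drop = FALSE])
  d_tail <- ttep_trend(coords[(F_ - k + 1L):F_, , , drop = FALSE])
  J <- dim(coords)[2]; C <- dim(coords)[3]
  out <- array(0, dim = c(F_ + 2L * P, J, C))
  out[(P + 1L):(P + F_), , ] <- coords
  sgn <- if (head_mode == "continuity") -1 else 1
  for (p in seq_len(P)) {
    # head position P + 1 - p holds the frame extrapolated p steps back
    out[P + 1L - p, , ] <- coords[1, , ] + sgn * p * d_head
    out[P + F_ + p, , ] <- coords[F_, , ] + p * d_tail
  }
  padded_sequence(out, F_, P)
}
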