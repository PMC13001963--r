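# Joint-level interpretability for a trained skeleton classifier.
#
# Gradient saliency differentiates the pre-sigmoid logit with respect to
# the (normalised) input coordinates and aggregates absolute gradients per
# joint; the logit rather than the probability is used so saturation does
# not flatten the map. Perturbation importance replaces one joint's
# coordinates at a time (zeroing, or adding Gaussian noise averaged over
# repeats) and records the absolute logit change. Both operate on the
# representation the model actually consumes.

new_saliency_map <- function(scores, method, normalization) {
  scores <- pmax(as.numeric(scores), 0)
  if (normalization == "max1" && max(scores) > 0) scores <- scores / max(scores)
  if (normalization == "sum1" && sum(scores) > 0) scores <- scores / sum(scores)
  structure(list(scores = scores, method = method,
                 normalization = normalization),
            class = "saliency_map")
}

#' Gradient-based joint saliency
#'
#' `score_j` is the aggregate (mean or max) over frames and coordinate
#' channels of the absolute gradient of the class-1 logit with respect to
#' joint j's input coordinates. Deterministic.
#'
#' @param model a trained `agtm_model`.
#' @param seq a pose sequence (2D or 3D matching the model input).
#' @param target_class 0 or 1; the sign of the differentiated logit (the
#'   magnitude map is identical for both classes).
#' @param reduce `"mean"` (default) or `"max"` aggregation.
#' @param normalization `"none"`, `"max1"` or `"sum1"`.
#' @return a `saliency_map` with one nonnegative score per joint.
#' @export
gradient_saliency <- function(model, seq, target_class = 1L,
                              reduce = c("mean", "max"),
                              normalization = c("none", "max1", "sum1")) {
  reduce <- match.arg(reduce)
  normalization <- match.arg(normalization)
  stopifnot(inherits(model, "agtm_model"))
  mat <- seq_to_norm_mat(seq, model$layout, velocity = model$config$clf_velocity)
  J <- model$layout$n_joints
  tape <- ag_tape()
  wp <- ag_wrap_params(tape, model$params)
  x <- ag_leaf(tape, mat)
  z <- agtm_logit(tape, wp, x, nrow(mat) %/% J, J, model$A0, model$lambda,
                  model$config)
  if (target_class == 0L) z <- ag_scale(tape, z, -1)
  ag_backward(tape, z)
  g <- abs(x$grad)
  agg <- if (reduce == "mean") mean else max
  scores <- vapply(seq_len(J), function(j) {
    rows <- seq(j, nrow(mat), by = J)
    agg(g[rows, , drop = FALSE])
  }, numeric(1))
  new_saliency_map(scores, "gradient", normalization)
}

#' Perturbation-based joint importance
#'
#' `score_j` is the mean absolute change of the class-1 logit when joint
#' j's (normalised) coordinates are replaced: zeroed under
#' `scheme = "zero"`, or shifted by Gaussian noise with standard deviation
#' `sigma`, averaged over `n_repeats` draws, under `scheme = "gaussian"`.
#' Deterministic given `seed`.
#'
#' @param model a trained `agtm_model`.
#' @param seq a pose sequence.
#' @param scheme `"zero"` or `"gaussian"`.
#' @param sigma noise standard deviation for the Gaussian scheme (> 0).
#' @param n_repeats Gaussian draws to average (>= 1).
#' @param seed integer seed.
#' @param normalization `"none"`, `"max1"` or `"sum1"`.
#' @return a `saliency_map`.
#' @export
perturbation_importance <- function(model, seq, scheme = c("zero", "gaussian"),
                                    sigma = 0.1, n_repeats = 5L, seed = 1L,
                                    normalization = c("none", "max1", "sum1")) {
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  stopifnot(inherits(model, "agtm_model"))
  if (scheme == "gaussian") {
    if (sigma <= 0) stop("sigma must be > 0")
    if (n_repeats < 1L) stop("n_repeats must be >= 1")
  }
  mat <- seq_to_norm_mat(seq, model$layout, velocity = model$config$clf_velocity)
  J <- model$layout$n_joints
  base <- agtm_score(model, mat, as_matrix = TRUE)
  set.seed(as.integer(seed))
  scores <- vapply(seq_len(J), function(j) {
    rows <- seq(j, nrow(mat), by = J)
    if (scheme == "zero") {
      pert <- mat
      pert[rows, ] <- 0
      abs(agtm_score(model, pert, as_matrix = TRUE) - base)
    } else {
      mean(vapply(seq_len(n_repeats), function(r) {
        pert <- mat
        pert[rows, ] <- pert[rows, ] +
          stats::rnorm(length(rows) * ncol(mat), 0, sigma)
        abs(agtm_score(model, pert, as_matrix = TRUE) - base)
      }, numeric(1)))
    }
  }, numeric(1))
  new_saliency_map(scores, "perturbation", normalization)
}

#' Top-k joints of a saliency map
#'
#' Indices (1-based) of the k largest scores; ties are broken by ascending
#' joint index for reproducibility.
#'
#' @param map a `saliency_map`.
#' @param k number of joints, `1 <= k <= J`.
#' @return integer vector of k joint indices, most salient first.
#' @export
top_joints <- function(map, k) {
  stopifnot(inherits(map, "saliency_map"))
  J <- length(map$scores)
  k <- as.integer(k)
  if (k < 1L || k > J) stop("k out of range")
  order(-map$scores, seq_len(J))[seq_len(k)]
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map> method=", x$method, ", ", length(x$scores),
      " joints, top = ", paste(top_joints(x, min(5L, length(x$scores))),
                               collapse = ", "), "\n", sep = "")
  invisible(x)
}
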