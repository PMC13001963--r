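# Pose-estimation evaluation metrics.
#
# MPJPE is the mean Euclidean distance between predicted and ground-truth
# joint positions over all frames and joints; PCK the fraction of joints
# whose error is strictly below a distance threshold (150 by convention,
# in input units); AUC the mean of the PCK curve over an increasing
# threshold grid up to the maximum threshold (the standard 5-unit steps to
# 150). Threshold comparisons are strict (<), matching the published
# definition -- ties at the threshold count as incorrect.

pose_errors <- function(pred, truth) {
  p <- if (inherits(pred, "pose_sequence_3d")) pred$coords else pred
  t_ <- if (inherits(truth, "pose_sequence_3d")) truth$coords else truth
  if (!all(dim(p) == dim(t_))) stop("shape mismatch between pred and truth")
  d <- p - t_
  sqrt(apply(d^2, c(1, 2), sum))   # F x J per-joint distances
}

#' Mean per-joint position error
#'
#' @param pred,truth `pose_sequence_3d` objects or F x J x 3 arrays of
#'   matching shape.
#' @return mean Euclidean per-joint error, in input units.
#' @export
mpjpe <- function(pred, truth) {
  mean(pose_errors(pred, truth))
}

#' Percentage of correct keypoints
#'
#' @inheritParams mpjpe
#' @param threshold distance threshold (> 0); a joint counts as correct iff
#'   its error is strictly below it.
#' @return fraction in `[0, 1]`.
#' @export
pck <- function(pred, truth, threshold = 150) {
  if (threshold <= 0) stop("threshold must be > 0")
  mean(pose_errors(pred, truth) < threshold)
}

#' Area under the PCK-threshold curve
#'
#' Discrete normalization of the PCK integral: the mean of `pck()` over the
#' positive thresholds of an increasing grid ending at the maximum
#' threshold.
#'
#' @inheritParams mpjpe
#' @param grid increasing threshold grid; zeros are dropped before
#'   averaging. Default `seq(5, 150, by = 5)`.
#' @return value in `[0, 1]`.
#' @export
auc_pck <- function(pred, truth, grid = seq(5, 150, by = 5)) {
  grid <- grid[grid > 0]
  if (!length(grid)) stop("threshold grid must contain positive values")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  err <- pose_errors(pred, truth)
  mean(vapply(grid, function(tau) mean(err < tau), numeric(1)))
}

#' Summary of pose-estimation error metrics
#'
#' @inheritParams mpjpe
#' @param threshold PCK threshold.
#' @param grid AUC threshold grid.
#' @return an object of class `pose_error_summary` with fields `mpjpe`,
#'   `pck`, `auc`, `threshold` and `thresholds_grid`.
#' @export
pose_error_summary <- function(pred, truth, threshold = 150,
                               grid = seq(5, 150, by = 5)) {
  structure(list(mpjpe = mpjpe(pred, truth),
                 pck = pck(pred, truth, threshold),
                 auc = auc_pck(pred, truth, grid),
                 threshold = threshold, thresholds_grid = grid),
            class = "pose_error_summary")
}

#' @export
print.pose_error_summary <- function(x, ...) {
  cat(sprintf("<pose_error_summary> MPJPE %.4f | PCK@%g %.4f | AUC %.4f\n",
              x$mpjpe, x$threshold, x$pck, x$auc))
  invisible(x)
}
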