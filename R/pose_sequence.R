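#' 2D pose sequence with per-joint confidences
#'
#' Frame-indexed 2D keypoints in normalized camera units, with a confidence
#' in `[0, 1]` per joint and frame, and an `observed` mask. Unobserved
#' entries carry confidence 0 and zero-filled coordinates; downstream code
#' must consult the mask, never sentinel values.
#'
#' @param coords numeric F x J x 2 array.
#' @param confidence numeric F x J matrix in `[0, 1]`; defaults to all 1.
#' @param observed logical F x J matrix; defaults to `confidence > 0`.
#' @return an object of class `pose_sequence_2d`.
#' @export
pose_sequence_2d <- function(coords, confidence = NULL, observed = NULL) {
  coords <- validate_coords(coords, 2L)
  dm <- dim(coords)
  F_ <- dm[1]; J <- dm[2]
  if (is.null(confidence)) confidence <- matrix(1, F_, J)
  confidence <- as.matrix(confidence)
  if (!all(dim(confidence) == c(F_, J))) stop("confidence shape mismatch")
  if (anyNA(confidence) || any(confidence < 0 | confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  if (is.null(observed)) observed <- confidence > 0
  observed <- as.matrix(observed)
  if (!all(dim(observed) == c(F_, J))) stop("observed shape mismatch")
  storage.mode(observed) <- "logical"
  if (any(!observed & confidence != 0)) {
    stop("unobserved entries must have confidence 0")
  }
  obs3 <- array(rep(observed, 2L), dim = dm)
  if (anyNA(coords[obs3])) stop("NaN coordinates in observed entries")
  structure(list(coords = coords, confidence = confidence,
                 observed = observed, n_frames = F_, n_joints = J),
            class = "pose_sequence_2d")
}

#' 3D pose sequence
#'
#' @param coords numeric F x J x 3 array (millimetres for real data,
#'   abstract units for synthetic data; metrics report in input units).
#' @param root_relative logical, whether coordinates are root-centred.
#' @return an object of class `pose_sequence_3d`.
#' @export
pose_sequence_3d <- function(coords, root_relative = FALSE) {
  coords <- validate_coords(coords, 3L)
  if (!all(is.finite(coords))) stop("3D coordinates must be finite")
  structure(list(coords = coords, root_relative = isTRUE(root_relative),
                 n_frames = dim(coords)[1], n_joints = dim(coords)[2]),
            class = "pose_sequence_3d")
}

validate_coords <- function(coords, C) {
  if (!is.array(coords) || length(dim(coords)) != 3L) {
    stop("coords must be an F x J x C array")
  }
  if (dim(coords)[3] != C) {
    stop(sprintf("dimension mismatch: expected %d coordinate channels, got %d",
                 C, dim(coords)[3]))
  }
  if (dim(coords)[1] < 1L) stop("no frames")
  storage.mode(coords) <- "double"
  coords
}

#' Boundary-padded sequence
#'
#' Wraps a coordinate array of length `F + 2P` together with the original
#' length `F` and the pad count `P`. The central `F` frames always equal the
#' source sequence exactly.
#'
#' @param coords (F + 2P) x J x C array.
#' @param original_length original frame count F.
#' @param pad pad count P on each side.
#' @return an object of class `padded_sequence`.
#' @export
padded_sequence <- function(coords, original_length, pad) {
  if (!is.array(coords) || length(dim(coords)) != 3L) {
    stop("coords must be a 3-d array")
  }
  if (dim(coords)[1] != original_length + 2L * pad) {
    stop("padded length must be F + 2P")
  }
  structure(list(coords = coords, original_length = as.integer(original_length),
                 pad = as.integer(pad)),
            class = "padded_sequence")
}

#' Labelled sequence dataset for binary classification
#'
#' @param sequences list of `pose_sequence_2d` / `pose_sequence_3d`.
#' @param labels integer vector of 0/1 labels, one per sequence.
#' @param task_name character label for the task.
#' @param require_both_classes if `TRUE` (default) insist on at least one
#'   sample per class, as training requires.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sequences, labels, task_name = "task",
                            require_both_classes = TRUE) {
  labels <- as.integer(labels)
  if (length(sequences) != length(labels)) stop("one label per sequence required")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (require_both_classes && length(unique(labels)) < 2L) {
    stop("at least one sample per class required")
  }
  structure(list(sequences = sequences, labels = labels,
                 task_name = task_name),
            class = "labeled_dataset")
}

#' @export
print.pose_sequence_2d <- function(x, ...) {
  cat("<pose_sequence_2d> ", x$n_frames, " frames x ", x$n_joints, " joints; ",
      sum(!x$observed), " unobserved entries\n", sep = "")
  invisible(x)
}

#' @export
print.pose_sequence_3d <- function(x, ...) {
  cat("<pose_sequence_3d> ", x$n_frames, " frames x ", x$n_joints,
      " joints\n", sep = "")
  invisible(x)
}

# flatten F x J x C to F x (J*C), joint-major column grouping
flatten_coords <- function(coords) {
  dm <- dim(coords)
  out <- matrix(0, dm[1], dm[2] * dm[3])
  for (j in seq_len(dm[2])) {
    out[, ((j - 1L) * dm[3] + 1L):(j * dm[3])] <- coords[, j, ]
  }
  out
}

unflatten_coords <- function(mat, J, C) {
  F_ <- nrow(mat)
  out <- array(0, dim = c(F_, J, C))
  for (j in seq_len(J)) {
    out[, j, ] <- mat[, ((j - 1L) * C + 1L):(j * C)]
  }
  out
}
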