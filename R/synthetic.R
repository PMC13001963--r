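# Synthetic skeleton motion.
#
# 3D joint trajectories are sums of per-joint sinusoids plus linear drift
# plus Gaussian noise -- enough temporal structure (smoothness, local linear
# trends, multi-scale periodicity) for every pipeline stage to be exercised,
# while staying a pure function of (params, seed). The 2D view is the
# orthographic x-y projection. Occlusion follows the random-missing-joints
# protocol: a fixed number of joints is dropped uniformly at random in each
# frame (an optional contiguous-block mode exists for stress tests).

#' Motion generator parameters
#'
#' @param n_frames sequence length F (>= 4).
#' @param amplitude_range range of per-joint sinusoid amplitudes.
#' @param frequency_range range of per-joint frequencies (cycles/sequence).
#' @param drift_range range of per-axis linear drift velocity (units/frame).
#' @param noise_sd standard deviation of i.i.d. Gaussian coordinate noise.
#' @return an object of class `motion_params`.
#' @export
motion_params <- function(n_frames = 81L, amplitude_range = c(0.5, 1.5),
                          frequency_range = c(0.5, 3), drift_range = c(-0.01, 0.01),
                          noise_sd = 0.02) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 4L) stop("n_frames must be >= 4")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_frames = n_frames,
                 amplitude_range = sort(amplitude_range),
                 frequency_range = sort(frequency_range),
                 drift_range = sort(drift_range),
                 noise_sd = noise_sd),
            class = "motion_params")
}

#' Two-class effect specification
#'
#' Class 1 scales the sinusoid amplitude and drift velocity of the
#' discriminative joints by `effect_size`; all other joints are identically
#' distributed across classes. `effect_size = 1` yields the null (the two
#' classes are indistinguishable by construction).
#'
#' @param discriminative_joints 1-based joint indices carrying the effect.
#' @param effect_size multiplicative amplitude/velocity factor (> 0).
#' @param n_per_class samples per class (>= 1).
#' @return an object of class `class_effect`.
#' @export
class_effect <- function(discriminative_joints, effect_size = 2,
                         n_per_class = 20L) {
  if (effect_size <= 0) stop("effect_size must be > 0")
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  discriminative_joints <- as.integer(discriminative_joints)
  if (length(discriminative_joints) == 0L && effect_size != 1) {
    stop("empty discriminative set with effect_size != 1")
  }
  structure(list(discriminative_joints = discriminative_joints,
                 effect_size = effect_size, n_per_class = n_per_class),
            class = "class_effect")
}

# Core trajectory builder; amp_scale/drift_scale are per-joint multipliers.
#
# Each joint carries one oscillation (amplitude, frequency, phase) expressed
# on all three axes through fixed phase offsets (0, pi/2, pi/4), plus a
# per-axis base position and linear drift whose depth component is the mean
# of the planar components. Every axis is therefore a sinusoid plus drift
# plus noise, while depth remains a deterministic function of the planar
# motion -- the orthographic 2D view determines 3D up to noise, which keeps
# the lifting task well-posed.
gen_coords3d <- function(layout, params, amp_scale = NULL, drift_scale = NULL) {
  F_ <- params$n_frames
  J <- layout$n_joints
  if (is.null(amp_scale)) amp_scale <- rep(1, J)
  if (is.null(drift_scale)) drift_scale <- rep(1, J)
  tt <- seq_len(F_) - 1L
  coords <- array(0, dim = c(F_, J, 3L))
  base <- matrix(stats::runif(J * 3L, -1, 1), J, 3L)
  axis_phase <- c(0, pi / 2, pi / 4)
  for (j in seq_len(J)) {
    A <- stats::runif(1, params$amplitude_range[1], params$amplitude_range[2]) *
      amp_scale[j]
    fr <- stats::runif(1, params$frequency_range[1], params$frequency_range[2])
    ph <- stats::runif(1, 0, 2 * pi)
    v <- stats::runif(2, params$drift_range[1], params$drift_range[2]) *
      drift_scale[j]
    v <- c(v, mean(v))
    theta <- 2 * pi * fr * tt / F_ + ph
    for (c in 1:3) {
      coords[, j, c] <- base[j, c] + A * sin(theta + axis_phase[c]) + v[c] * tt
    }
  }
  if (params$noise_sd > 0) {
    coords <- coords + array(stats::rnorm(length(coords), 0, params$noise_sd),
                             dim = dim(coords))
  }
  coords
}

#' Generate a paired 3D/2D synthetic pose sequence
#'
#' The 2D sequence is the orthographic x-y projection of the 3D one, with
#' all confidences 1. Deterministic given `seed`.
#'
#' @param layout a `joint_layout`.
#' @param params a `motion_params`.
#' @param seed integer seed.
#' @return a list with elements `pose3d` (`pose_sequence_3d`) and `pose2d`
#'   (`pose_sequence_2d`).
#' @export
gen_pose_sequence <- function(layout, params = motion_params(), seed = 1L) {
  withr_seed(seed)
  coords <- gen_coords3d(layout, params)
  pose3d <- pose_sequence_3d(coords)
  pose2d <- pose_sequence_2d(coords[, , 1:2, drop = FALSE])
  list(pose3d = pose3d, pose2d = pose2d)
}

# local RNG scoping without pulling in withr
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Apply per-frame random joint occlusion
#'
#' Each frame has exactly `n_missing` joints marked unobserved: confidence
#' set to 0 and coordinates zero-filled (downstream code must consult the
#' mask). Joints are chosen uniformly at random and independently per frame
#' (`mode = "iid"`, the benchmark protocol) or as one random contiguous run
#' of joint indices per frame (`mode = "block"`, a stress-test variant with
#' the same per-frame count).
#'
#' @param seq a `pose_sequence_2d`.
#' @param n_missing number of joints to drop per frame, `0 <= n <= J`.
#' @param seed integer seed.
#' @param mode `"iid"` (default) or `"block"`.
#' @return an occluded `pose_sequence_2d`.
#' @export
apply_occlusion <- function(seq, n_missing, seed = 1L, mode = c("iid", "block")) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "pose_sequence_2d"))
  n_missing <- as.integer(n_missing)
  J <- seq$n_joints
  if (n_missing < 0L || n_missing > J) stop("n_missing must lie in [0, J]")
  if (n_missing == 0L) return(seq)
  withr_seed(seed)
  coords <- seq$coords
  conf <- seq$confidence
  obs <- seq$observed
  for (f in seq_len(seq$n_frames)) {
    drop <- if (mode == "iid") {
      sample.int(J, n_missing)
    } else {
      start <- sample.int(J - n_missing + 1L, 1L)
      start:(start + n_missing - 1L)
    }
    coords[f, drop, ] <- 0
    conf[f, drop] <- 0
    obs[f, drop] <- FALSE
  }
  pose_sequence_2d(coords, conf, obs)
}

#' Generate a two-class synthetic classification dataset
#'
#' Class 0 uses the base motion parameters; class 1 multiplies the
#' amplitude and drift velocity of the discriminative joints by the effect
#' size. Labels are balanced and the generator is deterministic given
#' `seed`.
#'
#' @param layout a `joint_layout`.
#' @param effect a `class_effect`.
#' @param params a `motion_params`.
#' @param seed integer seed.
#' @param task_name task label stored on the dataset.
#' @return a `labeled_dataset` of `pose_sequence_3d` objects.
#' @export
gen_classification_dataset <- function(layout, effect, params = motion_params(),
                                       seed = 1L, task_name = "synthetic") {
  stopifnot(inherits(effect, "class_effect"))
  J <- layout$n_joints
  if (length(effect$discriminative_joints) &&
      (min(effect$discriminative_joints) < 1L ||
       max(effect$discriminative_joints) > J)) {
    stop("discriminative joints must index layout joints")
  }
  withr_seed(seed)
  scale1 <- rep(1, J)
  scale1[effect$discriminative_joints] <- effect$effect_size
  n <- effect$n_per_class
  sequences <- vector("list", 2L * n)
  labels <- integer(2L * n)
  for (i in seq_len(2L * n)) {
    lab <- as.integer(i > n)
    amp <- if (lab == 1L) scale1 else rep(1, J)
    sequences[[i]] <- pose_sequence_3d(
      gen_coords3d(layout, params, amp_scale = amp, drift_scale = amp))
    labels[i] <- lab
  }
  perm <- sample.int(2L * n)
  labeled_dataset(sequences[perm], labels[perm], task_name = task_name)
}
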