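#' Skeleton joint layout
#'
#' A joint layout names the joints of a skeleton and encodes the kinematic
#' tree through a parent pointer per joint (the root has parent `-1`,
#' 0-based). The layout defines the static graph used by the classifier's
#' adjacency matrix and the left/right pairing used by flip augmentation.
#'
#' @param joint_names character vector of J joint names.
#' @param parents integer vector of J 0-based parent indices; exactly one
#'   entry must be `-1` (the root).
#' @param left_right optional two-column matrix of 1-based joint indices
#'   pairing left/right joints for horizontal-flip augmentation.
#' @return an object of class `joint_layout` with fields `joint_names`,
#'   `parents`, `root_index` (0-based), `edges` (two-column 1-based
#'   child/parent matrix) and `n_joints`.
#' @examples
#' lay <- joint_layout(c("a", "b", "c"), c(-1L, 0L, 1L))
#' lay$n_joints
#' @export
joint_layout <- function(joint_names, parents, left_right = NULL) {
  joint_names <- as.character(joint_names)
  parents <- as.integer(parents)
  J <- length(joint_names)
  if (length(parents) != J) stop("joint_names and parents must have equal length")
  roots <- which(parents == -1L)
  if (length(roots) != 1L) stop("layout must have exactly one root (parent -1)")
  if (any(parents < -1L | parents >= J)) stop("parent indices out of range")
  # walk up from every joint; a cycle or disconnection would fail to reach root
  for (j in seq_len(J)) {
    cur <- j - 1L
    steps <- 0L
    while (cur != -1L) {
      cur <- parents[cur + 1L]
      steps <- steps + 1L
      if (steps > J) stop("parents do not encode a tree (cycle detected)")
    }
  }
  edges <- cbind(child = which(parents != -1L),
                 parent = parents[parents != -1L] + 1L)
  structure(
    list(joint_names = joint_names, parents = parents,
         root_index = roots - 1L, edges = edges, n_joints = J,
         left_right = left_right),
    class = "joint_layout"
  )
}

#' Default 17-joint skeleton layout
#'
#' The standard 17-joint tree used for lifting benchmarks: pelvis root, a
#' spine-thorax-neck-head chain with a nose branch, two legs
#' (hip-knee-ankle) and two arms (shoulder-elbow-wrist).
#'
#' Index (0-based) map: 0 pelvis, 1 r_hip, 2 r_knee, 3 r_ankle, 4 l_hip,
#' 5 l_knee, 6 l_ankle, 7 spine, 8 thorax, 9 neck, 10 head, 11 l_shoulder,
#' 12 l_elbow, 13 l_wrist, 14 r_shoulder, 15 r_elbow, 16 r_wrist.
#'
#' @return a `joint_layout` with 17 joints.
#' @export
default_joint_layout <- function() {
  names17 <- c("pelvis", "r_hip", "r_knee", "r_ankle",
               "l_hip", "l_knee", "l_ankle",
               "spine", "thorax", "neck", "head",
               "l_shoulder", "l_elbow", "l_wrist",
               "r_shoulder", "r_elbow", "r_wrist")
  parents17 <- c(-1L, 0L, 1L, 2L,
                 0L, 4L, 5L,
                 0L, 7L, 8L, 9L,
                 8L, 11L, 12L,
                 8L, 14L, 15L)
  lr <- cbind(left  = c(5L, 6L, 7L, 12L, 13L, 14L),
              right = c(2L, 3L, 4L, 15L, 16L, 17L))
  joint_layout(names17, parents17, left_right = lr)
}

#' @export
print.joint_layout <- function(x, ...) {
  cat("<joint_layout> ", x$n_joints, " joints, root = ",
      x$joint_names[x$root_index + 1L], "\n", sep = "")
  invisible(x)
}
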