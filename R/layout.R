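#' The 18-keypoint body layout
#'
#' Joint ordering, left/right pairing and the leg/feet index sets for the
#' 18-keypoint planar body model used by common multi-person pose trackers
#' (nose, neck, shoulders, elbows, wrists, hips, knees, ankles, eyes, ears),
#' each joint carrying a detection confidence.
#'
#' @return A list of class `joint_layout` with components:
#'   \describe{
#'     \item{names}{character(18), joint names in storage order.}
#'     \item{left_right_pairs}{integer matrix, one row per (left, right) pair.}
#'     \item{feet}{integer(2), ankle indices.}
#'     \item{legs}{integer(4), knee and ankle indices.}
#'     \item{neck, l_shoulder, r_shoulder, l_hip, r_hip}{scalar indices used
#'       by the normalization step.}
#'   }
#' @export
#' @examples
#' lay <- joint_layout()
#' lay$names[lay$feet]
joint_layout <- function() {
  names <- c("Nose", "Neck",
             "RShoulder", "RElbow", "RWrist",
             "LShoulder", "LElbow", "LWrist",
             "RHip", "RKnee", "RAnkle",
             "LHip", "LKnee", "LAnkle",
             "REye", "LEye", "REar", "LEar")
  pairs <- rbind(
    c(6L, 3L),   # shoulders (left, right)
    c(7L, 4L),   # elbows
    c(8L, 5L),   # wrists
    c(12L, 9L),  # hips
    c(13L, 10L), # knees
    c(14L, 11L), # ankles
    c(16L, 15L), # eyes
    c(18L, 17L)  # ears
  )
  colnames(pairs) <- c("left", "right")
  structure(list(
    names = names,
    left_right_pairs = pairs,
    feet = c(11L, 14L),
    legs = c(10L, 11L, 13L, 14L),
    neck = 2L,
    l_shoulder = 6L, r_shoulder = 3L,
    l_hip = 12L, r_hip = 9L
  ), class = "joint_layout")
}

#' @export
print.joint_layout <- function(x, ...) {
  cat("18-keypoint planar body layout\n")
  cat("  joints:", paste(x$names, collapse = ", "), "\n")
  cat("  feet:", paste(x$names[x$feet], collapse = ", "),
      " legs:", paste(x$names[x$legs], collapse = ", "), "\n")
  invisible(x)
}

# number of joints / token width used throughout
N_JOINTS <- 18L
TOKEN_DIM <- 54L
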