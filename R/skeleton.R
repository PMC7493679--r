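#' Canonical 20-joint skeleton
#'
#' The tracked point-light marker set used throughout the package: head, neck,
#' mid spine, pelvis, and left/right shoulder, elbow, wrist, hand (fingertip),
#' hip, knee, ankle and foot (toe). All skeleton files and in-memory sequences
#' store joints in exactly this order.
#'
#' @return Character vector of the 20 canonical joint names, in order.
#' @export
canonical_joints <- function() {
  c(
    "head", "neck", "spine_mid", "pelvis",
    "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
    "wrist_l", "wrist_r", "hand_l", "hand_r",
    "hip_l", "hip_r", "knee_l", "knee_r",
    "ankle_l", "ankle_r", "foot_l", "foot_r"
  )
}

AXES <- c("x", "y", "z")

#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds the timestamped 3D trajectories of the 20
#' canonical joints for one walking session, in meters, under the axis
#' convention x lateral (+right), y vertical (+up), z anterior (+toward the
#' viewer). Walkers are treadmill-bound: the pelvis has no progressive
#' anterior drift.
#'
#' @param timestamps Numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param positions Numeric array `frames x 20 x 3` of joint coordinates in
#'   meters, joints in [canonical_joints()] order, axes (x, y, z).
#' @param subject_id,session_id,gender Metadata: identifiers and the binary
#'   gender label (`"M"` or `"F"`).
#' @param fps Nominal capture rate in frames per second.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(timestamps, positions, subject_id = NA_character_,
                              session_id = NA_character_, gender = NA_character_,
                              fps = NA_real_) {
  if (!is.array(positions) || length(dim(positions)) != 3L) {
    stop("`positions` must be a frames x 20 x 3 array", call. = FALSE)
  }
  d <- dim(positions)
  if (d[2] != 20L || d[3] != 3L) {
    stop(sprintf(
      "skeleton must have exactly 20 joints and 3 axes, got %d x %d",
      d[2], d[3]
    ), call. = FALSE)
  }
  if (length(timestamps) != d[1]) {
    stop("length(timestamps) must equal the number of frames", call. = FALSE)
  }
  if (d[1] > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (anyNA(positions) || any(!is.finite(positions))) {
    stop("positions contain missing or non-finite coordinates", call. = FALSE)
  }
  dimnames(positions) <- list(NULL, canonical_joints(), AXES)
  structure(
    list(
      timestamps = as.numeric(timestamps),
      positions = positions,
      subject_id = subject_id,
      session_id = session_id,
      gender = gender,
      fps = as.numeric(fps)
    ),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf(
    "<skeleton_sequence> %d frames x 20 joints, %.3g s @ %s fps [subject %s, session %s, gender %s]\n",
    n_frames(x), diff(range(x$timestamps)),
    format(x$fps), x$subject_id, x$session_id, x$gender
  ))
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence") || inherits(seq, "skeleton_sequence_2d"))
  dim(seq$positions)[1]
}

#' Flatten a skeleton sequence to a frames x 60 matrix
#'
#' Per-frame vector layout is joint-major: for each joint in canonical order,
#' its (x, y, z) coordinates, giving columns `head_x, head_y, head_z, neck_x,
#' ...` (cardinality 60 in 3D, 40 after [project_coronal()]).
#'
#' @param seq A `skeleton_sequence` (3D or coronal 2D).
#' @return Numeric matrix, one row per frame, named columns.
#' @export
as_frame_matrix <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence") || inherits(seq, "skeleton_sequence_2d"))
  pos <- seq$positions
  d <- dim(pos)
  axes <- dimnames(pos)[[3]]
  out <- matrix(aperm(pos, c(1, 3, 2)), nrow = d[1], ncol = d[2] * d[3])
  colnames(out) <- as.vector(t(outer(dimnames(pos)[[2]], axes, paste, sep = "_")))
  out
}

# Replace the position array of a sequence, keeping metadata.
set_positions <- function(seq, positions) {
  seq$positions <- positions
  dimnames(seq$positions) <- list(NULL, canonical_joints(), AXES[seq_len(dim(positions)[3])])
  seq
}
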