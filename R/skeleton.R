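#' Raw pose tracklet
#'
#' One tracked person's per-frame skeletons as produced by a multi-person
#' pose tracker: planar joint coordinates with per-joint confidences, optional
#' per-frame bounding boxes, the source stream's frame rate and a track id.
#'
#' @param data numeric array `T x 18 x 3`; per frame, columns are
#'   (x, y, confidence) for the 18 joints of [joint_layout()].
#' @param fps frames per second of the source stream, `> 0`.
#' @param track_id opaque identifier for the tracked person.
#' @param bbox optional `T x 4` matrix of per-frame boxes `(x, y, w, h)` in px.
#' @param frame_index optional strictly increasing integer vector of source
#'   frame indices (0-based); defaults to `0:(T-1)`.
#' @return An object of class `gait_tracklet`.
#' @export
gait_tracklet <- function(data, fps, track_id = "track", bbox = NULL,
                          frame_index = NULL) {
  data <- as_skeleton_array(data)
  n <- dim(data)[1L]
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number")
  if (!is.null(bbox)) {
    bbox <- as.matrix(bbox)
    if (nrow(bbox) != n || ncol(bbox) != 4L)
      stop("bbox must be a T x 4 matrix aligned with frames")
  }
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n || (n > 1L && any(diff(frame_index) <= 0L)))
    stop("frame_index must be strictly increasing and match the frame count")
  conf <- data[, , 3L, drop = FALSE]
  if (any(conf < 0 | conf > 1)) stop("confidences must lie in [0, 1]")
  if (any(!is.finite(data))) stop("coordinates must be finite")
  structure(list(data = data, fps = fps, track_id = as.character(track_id),
                 bbox = bbox, frame_index = frame_index),
            class = "gait_tracklet")
}

as_skeleton_array <- function(data) {
  data <- unname(as.array(data))
  d <- dim(data)
  if (length(d) == 2L && all(d == c(N_JOINTS, 3L))) {
    data <- array(data, dim = c(1L, N_JOINTS, 3L))
    d <- dim(data)
  }
  if (length(d) != 3L || d[2L] != N_JOINTS || d[3L] != 3L)
    stop("skeleton data must be a T x 18 x 3 array")
  storage.mode(data) <- "double"
  data
}

#' @export
print.gait_tracklet <- function(x, ...) {
  cat(sprintf("<gait_tracklet '%s': %d frames @ %g fps%s>\n",
              x$track_id, dim(x$data)[1L], x$fps,
              if (is.null(x$bbox)) "" else ", with bboxes"))
  invisible(x)
}

#' @export
length.gait_tracklet <- function(x) dim(x$data)[1L]

#' Normalized skeleton sequence
#'
#' A pelvis-centered, shoulder/torso-scaled skeleton sequence at the
#' reference pace. Per frame the pelvis (hip midpoint) maps to the origin,
#' the shoulder span maps to 1 horizontal unit and the neck--pelvis distance
#' to 1 vertical unit. Confidences are carried through unchanged.
#'
#' @param data numeric `T x 18 x 3` array (x, y, confidence).
#' @param ref_fps reference pace in frames/second (default 24).
#' @param degenerate logical vector flagging frames whose scale denominators
#'   fell below the epsilon guard.
#' @return An object of class `gait_sequence`.
#' @export
gait_sequence <- function(data, ref_fps = 24, degenerate = NULL) {
  data <- as_skeleton_array(data)
  n <- dim(data)[1L]
  if (is.null(degenerate)) degenerate <- rep(FALSE, n)
  structure(list(data = data, ref_fps = ref_fps,
                 degenerate = as.logical(degenerate)),
            class = "gait_sequence")
}

#' @export
print.gait_sequence <- function(x, ...) {
  cat(sprintf("<gait_sequence: %d frames @ reference %g fps%s>\n",
              dim(x$data)[1L], x$ref_fps,
              if (any(x$degenerate)) sprintf(", %d degenerate", sum(x$degenerate)) else ""))
  invisible(x)
}

#' @export
length.gait_sequence <- function(x) dim(x$data)[1L]

#' Normalize a single skeleton frame
#'
#' Centers a skeleton at the pelvis (midpoint of the two hips) and scales the
#' horizontal axis by the shoulder span and the vertical axis by the
#' neck--pelvis distance:
#' `x' = (x - x_pelvis) / max(|x_Rshoulder - x_Lshoulder|, eps)` and
#' `y' = (y - y_pelvis) / max(|y_neck - y_pelvis|, eps)`.
#' This removes position, height and body-scale information while preserving
#' the movement pattern. Confidences are untouched.
#'
#' Frames whose denominators fall below `eps` (for instance a perfectly
#' frontal collapse of the shoulder span, or all joints coincident) are never
#' divided by zero: the guard denominator is used and the result is flagged
#' via the `"degenerate"` attribute. Dropping such frames is the filter
#' stage's decision, not this function's.
#'
#' @param frame numeric `18 x 3` matrix (x, y, confidence).
#' @param layout a [joint_layout()].
#' @param eps denominator guard (default `1e-6`).
#' @return An `18 x 3` matrix with attribute `degenerate` (logical).
#' @export
#' @examples
#' f <- matrix(0, 18, 3); lay <- joint_layout()
#' f[lay$l_hip, 1:2] <- c(9, 20); f[lay$r_hip, 1:2] <- c(11, 20)
#' f[lay$l_shoulder, 1:2] <- c(9, 18); f[lay$r_shoulder, 1:2] <- c(11, 18)
#' f[lay$neck, 1:2] <- c(10, 18)
#' normalize_frame(f)[lay$neck, ]  # neck at (0, -1)
normalize_frame <- function(frame, layout = joint_layout(), eps = 1e-6) {
  frame <- as.matrix(frame)
  if (nrow(frame) != N_JOINTS || ncol(frame) != 3L)
    stop("frame must be an 18 x 3 matrix")
  x_pelvis <- (frame[layout$l_hip, 1L] + frame[layout$r_hip, 1L]) / 2
  y_pelvis <- (frame[layout$l_hip, 2L] + frame[layout$r_hip, 2L]) / 2
  dx <- abs(frame[layout$r_shoulder, 1L] - frame[layout$l_shoulder, 1L])
  dy <- abs(frame[layout$neck, 2L] - y_pelvis)
  degenerate <- (dx < eps) || (dy < eps)
  out <- frame
  out[, 1L] <- (frame[, 1L] - x_pelvis) / max(dx, eps)
  out[, 2L] <- (frame[, 2L] - y_pelvis) / max(dy, eps)
  attr(out, "degenerate") <- degenerate
  out
}

#' Normalize every frame of a tracklet
#'
#' Applies [normalize_frame()] independently to each frame and wraps the
#' result as a [gait_sequence()]. The reference pace recorded on the output
#' is the tracklet's own fps; run [resample_tracklet()] first to unify pace.
#'
#' @param track a [gait_tracklet()].
#' @inheritParams normalize_frame
#' @return A [gait_sequence()].
#' @export
normalize_sequence <- function(track, layout = joint_layout(), eps = 1e-6) {
  stopifnot(inherits(track, "gait_tracklet"))
  n <- dim(track$data)[1L]
  if (n == 0L) stop("cannot normalize an empty tracklet")
  out <- track$data
  degenerate <- logical(n)
  for (t in seq_len(n)) {
    nf <- normalize_frame(track$data[t, , ], layout = layout, eps = eps)
    degenerate[t] <- attr(nf, "degenerate")
    out[t, , ] <- nf
  }
  gait_sequence(out, ref_fps = track$fps, degenerate = degenerate)
}

#' Resample a tracklet to a reference frame rate
#'
#' Linearly interpolates every coordinate and confidence channel on the time
#' axis so that the output covers the same wall-clock duration at `ref_fps`
#' frames per second. This unifies pace and duration across video streams
#' with heterogeneous frame rates; 24 fps is treated as real-time speed.
#'
#' @param track a [gait_tracklet()] with at least 2 frames.
#' @param ref_fps target frame rate (default 24).
#' @return A [gait_tracklet()] at `ref_fps`.
#' @export
resample_tracklet <- function(track, ref_fps = 24) {
  stopifnot(inherits(track, "gait_tracklet"))
  n <- dim(track$data)[1L]
  if (n < 2L) stop("resampling needs at least 2 frames")
  if (isTRUE(all.equal(track$fps, ref_fps))) return(track)
  # frame-count duration convention: n frames at fps span n/fps seconds,
  # so the resampled length is n * ref_fps / fps
  m <- max(2L, as.integer(round(n * ref_fps / track$fps)))
  span <- (n - 1) / track$fps                  # seconds between first/last sample
  t_src <- (seq_len(n) - 1) / track$fps
  t_out <- (seq_len(m) - 1) / ref_fps
  t_out[t_out > span] <- span                  # hold the last sample at the tail
  flat <- matrix(track$data, nrow = n)         # T x 54, channel-major columns
  out <- apply(flat, 2L, function(ch) stats::approx(t_src, ch, xout = t_out)$y)
  bbox <- NULL
  if (!is.null(track$bbox))
    bbox <- apply(track$bbox, 2L, function(ch) stats::approx(t_src, ch, xout = t_out)$y)
  dat <- array(out, dim = c(m, N_JOINTS, 3L))
  # interpolation cannot leave [0,1] but clamp fp dust on the conf channel
  dat[, , 3L] <- pmin(pmax(dat[, , 3L], 0), 1)
  gait_tracklet(dat, fps = ref_fps, track_id = track$track_id, bbox = bbox)
}

#' Deterministic center crop
#'
#' Returns the `T` frames in the middle of the sequence,
#' `[floor((L - T)/2), floor((L - T)/2) + T)` with 0-based half-open
#' indexing — the deterministic evaluation crop (no test-time augmentation).
#'
#' @param seq a [gait_sequence()] of length `>= T`.
#' @param T crop length in frames (default 48, about two gait cycles at
#'   24 fps).
#' @return A [gait_sequence()] of length exactly `T`.
#' @export
center_crop <- function(seq, T = 48L) {
  stopifnot(inherits(seq, "gait_sequence"))
  L <- dim(seq$data)[1L]
  if (L < T) stop(sprintf("sequence length %d is shorter than crop %d", L, T))
  start <- (L - T) %/% 2L            # 0-based
  idx <- seq.int(start + 1L, start + T)
  gait_sequence(seq$data[idx, , , drop = FALSE], ref_fps = seq$ref_fps,
                degenerate = seq$degenerate[idx])
}

#' Flatten a sequence to pose tokens
#'
#' Each skeleton frame becomes one 54-dimensional token: the (x, y,
#' confidence) triplets of the 18 joints concatenated in layout order.
#'
#' @param seq a [gait_sequence()].
#' @return A numeric `T x 54` matrix.
#' @seealso [unflatten_sequence()]
#' @export
flatten_sequence <- function(seq) {
  stopifnot(inherits(seq, "gait_sequence"))
  dat <- seq$data
  n <- dim(dat)[1L]
  out <- matrix(0, n, TOKEN_DIM)
  # joint-major triplets: columns (3j-2, 3j-1, 3j) = (x, y, c) of joint j
  out[, seq(1L, TOKEN_DIM, by = 3L)] <- dat[, , 1L]
  out[, seq(2L, TOKEN_DIM, by = 3L)] <- dat[, , 2L]
  out[, seq(3L, TOKEN_DIM, by = 3L)] <- dat[, , 3L]
  out
}

#' Rebuild a sequence from pose tokens
#'
#' Inverse of [flatten_sequence()].
#'
#' @param tokens numeric `T x 54` matrix.
#' @param ref_fps reference pace recorded on the result.
#' @return A [gait_sequence()].
#' @export
unflatten_sequence <- function(tokens, ref_fps = 24) {
  tokens <- as.matrix(tokens)
  if (ncol(tokens) != TOKEN_DIM) stop("tokens must have 54 columns")
  n <- nrow(tokens)
  dat <- array(0, dim = c(n, N_JOINTS, 3L))
  dat[, , 1L] <- tokens[, seq(1L, TOKEN_DIM, by = 3L)]
  dat[, , 2L] <- tokens[, seq(2L, TOKEN_DIM, by = 3L)]
  dat[, , 3L] <- tokens[, seq(3L, TOKEN_DIM, by = 3L)]
  gait_sequence(dat, ref_fps = ref_fps)
}

#' Average movement speed of the legs
#'
#' Mean over consecutive frame pairs of the mean Euclidean displacement of
#' the leg joints (both knees and both ankles), in normalized units per
#' frame. Low values indicate a standing person, implausibly high values
#' erratic pose-estimation output; the corpus filter keeps sequences within
#' a plausibility band.
#'
#' @param seq a [gait_sequence()] with at least 2 frames.
#' @param layout a [joint_layout()].
#' @return A single non-negative number.
#' @export
mean_leg_speed <- function(seq, layout = joint_layout()) {
  stopifnot(inherits(seq, "gait_sequence"))
  n <- dim(seq$data)[1L]
  if (n < 2L) stop("leg speed needs at least 2 frames")
  legs <- seq$data[, layout$legs, 1:2, drop = FALSE]
  d <- legs[-1L, , , drop = FALSE] - legs[-n, , , drop = FALSE]
  step <- sqrt(d[, , 1L, drop = FALSE]^2 + d[, , 2L, drop = FALSE]^2)
  mean(step)
}
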