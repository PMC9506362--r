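#' Training-time augmentation configuration
#'
#' The standard augmentation suite for skeleton sequences: random crops of
#' fixed length, random horizontal flips with 50% probability, random pace
#' changes, and Gaussian jitter on the joint coordinates. Pace changes are
#' applied first (they change the length), then crop, flip and jitter.
#'
#' @param crop_T crop length in frames (default 48).
#' @param flip_p horizontal flip probability.
#' @param pace_range multiplicative pace factor range `[lo, hi]` with
#'   `0 < lo <= 1 <= hi`.
#' @param noise_sigma standard deviation of the coordinate jitter, in
#'   normalized units.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(crop_T = 48L, flip_p = 0.5,
                           pace_range = c(0.75, 1.5), noise_sigma = 0.005) {
  stopifnot(pace_range[1] > 0, pace_range[1] <= 1, pace_range[2] >= 1,
            noise_sigma >= 0)
  structure(list(crop_T = as.integer(crop_T), flip_p = flip_p,
                 pace_range = pace_range, noise_sigma = noise_sigma),
            class = "augment_config")
}

#' Random contiguous crop
#'
#' Selects a contiguous window of `T` frames with the start index uniform
#' on `[0, L - T]` (0-based).
#'
#' @param seq a [gait_sequence()] of length `>= T`.
#' @param T crop length.
#' @return A [gait_sequence()] of length `T`.
#' @export
random_crop <- function(seq, T = 48L) {
  stopifnot(inherits(seq, "gait_sequence"))
  L <- dim(seq$data)[1L]
  if (L < T) stop(sprintf("sequence length %d shorter than crop %d", L, T))
  start <- sample.int(L - T + 1L, 1L)          # 1-based start in [1, L-T+1]
  idx <- seq.int(start, start + T - 1L)
  gait_sequence(seq$data[idx, , , drop = FALSE], ref_fps = seq$ref_fps,
                degenerate = seq$degenerate[idx])
}

#' Mirror a sequence horizontally
#'
#' Negates all x coordinates and swaps each left joint's (x, y, confidence)
#' triplet with its right partner: a mirrored left joint is the right
#' joint's measurement, so confidences travel with the coordinates. An
#' involution; it preserves [mean_leg_speed()] exactly.
#'
#' @param seq a [gait_sequence()].
#' @param layout a [joint_layout()].
#' @return The mirrored [gait_sequence()].
#' @export
horizontal_flip <- function(seq, layout = joint_layout()) {
  stopifnot(inherits(seq, "gait_sequence"))
  dat <- seq$data
  dat[, , 1L] <- -dat[, , 1L]
  p <- layout$left_right_pairs
  swapped <- dat
  swapped[, p[, "left"], ] <- dat[, p[, "right"], ]
  swapped[, p[, "right"], ] <- dat[, p[, "left"], ]
  gait_sequence(swapped, ref_fps = seq$ref_fps, degenerate = seq$degenerate)
}

#' Random pace change
#'
#' Rescales the time axis by a factor `f` drawn uniformly from
#' `pace_range`, via per-channel linear interpolation: `f > 1` speeds the
#' walk up (fewer frames), `f < 1` slows it down (more frames). Endpoints
#' are preserved. If the result would be shorter than `min_len`, the factor
#' is capped so the output just reaches `min_len`.
#'
#' @param seq a [gait_sequence()] with at least 2 frames.
#' @param pace_range factor range.
#' @param min_len minimum acceptable output length (typically the crop
#'   length); `NULL` disables the cap.
#' @return A [gait_sequence()] of length `round(L / f)`.
#' @export
random_pace <- function(seq, pace_range = c(0.75, 1.5), min_len = NULL) {
  stopifnot(inherits(seq, "gait_sequence"))
  L <- dim(seq$data)[1L]
  if (L < 2L) stop("pace change needs at least 2 frames")
  f <- stats::runif(1L, pace_range[1L], pace_range[2L])
  if (!is.null(min_len) && round(L / f) < min_len) f <- L / min_len
  m <- max(2L, as.integer(round(L / f)))
  if (m == L) return(seq)
  t_src <- seq(0, 1, length.out = L)
  t_out <- seq(0, 1, length.out = m)
  flat <- matrix(seq$data, nrow = L)
  out <- apply(flat, 2L, function(ch) stats::approx(t_src, ch, xout = t_out)$y)
  dat <- array(out, dim = c(m, N_JOINTS, 3L))
  dat[, , 3L] <- pmin(pmax(dat[, , 3L], 0), 1)
  gait_sequence(dat, ref_fps = seq$ref_fps)
}

#' Gaussian joint jitter
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to the x and y channels only; the
#' confidence channel is untouched.
#'
#' @param seq a [gait_sequence()].
#' @param sigma noise standard deviation in normalized units.
#' @return A [gait_sequence()].
#' @export
jitter_joints <- function(seq, sigma = 0.005) {
  stopifnot(inherits(seq, "gait_sequence"), sigma >= 0)
  if (sigma == 0) return(seq)
  dat <- seq$data
  n <- length(dat[, , 1:2])
  dat[, , 1:2] <- dat[, , 1:2] + stats::rnorm(n, 0, sigma)
  gait_sequence(dat, ref_fps = seq$ref_fps, degenerate = seq$degenerate)
}

# one augmentation draw: pace -> crop -> flip -> jitter
augment_once <- function(seq, cfg, layout = joint_layout()) {
  out <- random_pace(seq, cfg$pace_range, min_len = cfg$crop_T)
  out <- random_crop(out, cfg$crop_T)
  if (stats::runif(1L) < cfg$flip_p) out <- horizontal_flip(out, layout)
  jitter_joints(out, cfg$noise_sigma)
}

#' Two-view positive-pair sampler
#'
#' Draws two independent augmentations of the same tracklet's sequence,
#' both of length `crop_T`. The pair forms the positive pair for the
#' supervised contrastive objective; longer tracklets yield more variable
#' view pairs because the crop windows can land further apart.
#'
#' @param seq a [gait_sequence()] long enough for the crop.
#' @param cfg an [augment_config()].
#' @param layout a [joint_layout()].
#' @return List of two [gait_sequence()] objects.
#' @export
two_views <- function(seq, cfg = augment_config(), layout = joint_layout()) {
  list(augment_once(seq, cfg, layout), augment_once(seq, cfg, layout))
}
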