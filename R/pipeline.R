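#' Corpus construction configuration
#'
#' Thresholds and constants of the tracklet-cleaning pipeline. Defaults are
#' the values used to build large pose-tracker gait corpora: frames whose
#' mean joint confidence is below 0.5 or whose mean feet confidence is below
#' 0.4 are removed (equality is kept); tracklets shorter than
#' `period_T * fps / 24` source frames are dropped; everything is resampled
#' to 24 fps and normalized; finally sequences whose average leg speed falls
#' outside `[0.0015, 0.09]` normalized units/frame (standing or erratic
#' pose output) are removed.
#'
#' @param min_mean_conf minimum mean joint confidence per frame.
#' @param min_feet_conf minimum mean ankle confidence per frame.
#' @param period_T period length in frames at the reference pace.
#' @param ref_fps reference frame rate.
#' @param leg_speed_lo,leg_speed_hi keep-band for [mean_leg_speed()].
#' @param max_gap_fill interior gaps of at most this many frames left by
#'   frame removal are refilled by linear interpolation; longer gaps split
#'   the tracklet.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mean_conf = 0.5, min_feet_conf = 0.4,
                            period_T = 48L, ref_fps = 24,
                            leg_speed_lo = 0.0015, leg_speed_hi = 0.09,
                            max_gap_fill = 12L) {
  stopifnot(min_mean_conf >= 0, min_mean_conf <= 1,
            min_feet_conf >= 0, min_feet_conf <= 1,
            leg_speed_lo < leg_speed_hi, period_T > 0)
  structure(list(min_mean_conf = min_mean_conf, min_feet_conf = min_feet_conf,
                 period_T = as.integer(period_T), ref_fps = ref_fps,
                 leg_speed_lo = leg_speed_lo, leg_speed_hi = leg_speed_hi,
                 max_gap_fill = as.integer(max_gap_fill)),
            class = "pipeline_config")
}

# Shared frame-removal engine: drop frames failing `keep`, trim the ends,
# refill interior gaps <= max_gap_fill by linear interpolation on the frame
# axis, split at longer gaps. Returns a list of tracklets (possibly empty).
drop_frames <- function(track, keep, max_gap_fill = 12L) {
  n <- dim(track$data)[1L]
  if (all(keep)) return(list(track))
  if (!any(keep)) return(list())
  kept <- which(keep)
  # segment boundaries: gaps longer than max_gap_fill split the tracklet
  gaps <- diff(kept) - 1L
  seg_id <- cumsum(c(1L, as.integer(gaps > max_gap_fill)))
  out <- list()
  for (s in unique(seg_id)) {
    idx <- kept[seg_id == s]
    lo <- idx[1L]; hi <- idx[length(idx)]
    full <- seq.int(lo, hi)
    flat <- matrix(track$data[idx, , , drop = FALSE], nrow = length(idx))
    if (length(idx) == length(full)) {
      dat <- array(flat, dim = c(length(full), N_JOINTS, 3L))
      bbox <- if (is.null(track$bbox)) NULL else track$bbox[idx, , drop = FALSE]
    } else {
      # refill removed interior frames by per-channel linear interpolation
      filled <- apply(flat, 2L, function(ch) stats::approx(idx, ch, xout = full)$y)
      dat <- array(filled, dim = c(length(full), N_JOINTS, 3L))
      dat[, , 3L] <- pmin(pmax(dat[, , 3L], 0), 1)
      bbox <- if (is.null(track$bbox)) NULL else
        apply(track$bbox, 2L, function(ch) stats::approx(idx, ch[idx], xout = full)$y)
    }
    id <- if (length(unique(seg_id)) > 1L)
      paste0(track$track_id, ".", s) else track$track_id
    out[[length(out) + 1L]] <-
      gait_tracklet(dat, fps = track$fps, track_id = id,
                    bbox = bbox, frame_index = track$frame_index[full])
  }
  out
}

#' Remove frames with low overall joint confidence
#'
#' Frames whose mean confidence over the 18 joints is strictly below `thr`
#' are removed ("less than" semantics: equality is kept). Interior gaps of
#' at most `max_gap_fill` frames are refilled by linear interpolation;
#' longer gaps split the tracklet into independent tracklets.
#'
#' @param track a [gait_tracklet()].
#' @param thr confidence threshold (default 0.5).
#' @param max_gap_fill see [pipeline_config()].
#' @return A list of [gait_tracklet()] (empty if all frames were removed).
#' @export
drop_low_confidence_frames <- function(track, thr = 0.5, max_gap_fill = 12L) {
  stopifnot(inherits(track, "gait_tracklet"))
  mean_conf <- rowMeans(matrix(track$data[, , 3L], nrow = dim(track$data)[1L]))
  drop_frames(track, keep = mean_conf >= thr, max_gap_fill = max_gap_fill)
}

#' Remove frames with low feet confidence
#'
#' As [drop_low_confidence_frames()], but thresholding the mean confidence
#' of the two ankles (default 0.4). Confidently detected feet matter because
#' leg movement is the dominant signal for gait analysis.
#'
#' @inheritParams drop_low_confidence_frames
#' @param layout a [joint_layout()].
#' @export
drop_low_feet_confidence_frames <- function(track, thr = 0.4,
                                            max_gap_fill = 12L,
                                            layout = joint_layout()) {
  stopifnot(inherits(track, "gait_tracklet"))
  feet_conf <- rowMeans(matrix(track$data[, layout$feet, 3L],
                               nrow = dim(track$data)[1L]))
  drop_frames(track, keep = feet_conf >= thr, max_gap_fill = max_gap_fill)
}

#' Duration filter
#'
#' A tracklet is long enough when it has at least `period_T * fps / 24`
#' source frames, i.e. at least `period_T` frames once resampled to the
#' reference 24 fps pace. Equality is kept.
#'
#' @param track a [gait_tracklet()].
#' @param cfg a [pipeline_config()].
#' @return `TRUE` or `FALSE`.
#' @export
is_long_enough <- function(track, cfg = pipeline_config()) {
  stopifnot(inherits(track, "gait_tracklet"))
  dim(track$data)[1L] >= cfg$period_T * track$fps / 24
}

#' Leg-speed plausibility filter
#'
#' Keeps sequences whose [mean_leg_speed()] lies inside the configured
#' band: below it the person is standing, above it the pose output is
#' erratic.
#'
#' @param seq a [gait_sequence()].
#' @param cfg a [pipeline_config()].
#' @return `TRUE` or `FALSE`.
#' @export
passes_leg_speed <- function(seq, cfg = pipeline_config()) {
  v <- mean_leg_speed(seq)
  v >= cfg$leg_speed_lo && v <= cfg$leg_speed_hi
}

#' Build a gait corpus from raw tracklets
#'
#' Runs the full cleaning chain, in order: low-confidence frame removal,
#' low-feet-confidence frame removal, duration filter (in source-fps units),
#' resampling to the reference pace, per-frame normalization and the
#' leg-speed band filter. Survivors become corpus entries; each surviving
#' tracklet is treated as a unique identity. Per-stage removal counts are
#' recorded in `stats`.
#'
#' @param tracks list of [gait_tracklet()].
#' @param cfg a [pipeline_config()].
#' @param attributes optional named list/rows of per-tracklet attribute
#'   vectors (matched to input `track_id`s); survivors keep theirs.
#' @return An object of class `gait_dataset`: list with `sequences`
#'   (list of [gait_sequence()]), `ids` (character), `attributes` (matrix or
#'   `NULL`) and `stats` (named integer vector of per-stage removals).
#' @export
build_dataset <- function(tracks, cfg = pipeline_config(), attributes = NULL) {
  stats <- c(low_conf = 0L, low_feet_conf = 0L, short = 0L, speed = 0L)
  sequences <- list(); ids <- character(0); attr_rows <- list()
  for (track in tracks) {
    pieces <- drop_low_confidence_frames(track, cfg$min_mean_conf, cfg$max_gap_fill)
    if (length(pieces) == 0L) { stats["low_conf"] <- stats["low_conf"] + 1L; next }
    pieces <- unlist(lapply(pieces, drop_low_feet_confidence_frames,
                            thr = cfg$min_feet_conf, max_gap_fill = cfg$max_gap_fill),
                     recursive = FALSE)
    if (length(pieces) == 0L) { stats["low_feet_conf"] <- stats["low_feet_conf"] + 1L; next }
    survived <- FALSE
    for (piece in pieces) {
      if (!is_long_enough(piece, cfg)) { stats["short"] <- stats["short"] + 1L; next }
      piece <- resample_tracklet(piece, cfg$ref_fps)
      seq <- normalize_sequence(piece)
      if (!passes_leg_speed(seq, cfg)) { stats["speed"] <- stats["speed"] + 1L; next }
      sequences[[length(sequences) + 1L]] <- seq
      ids <- c(ids, piece$track_id)
      if (!is.null(attributes))
        attr_rows[[length(attr_rows) + 1L]] <- attributes[[track$track_id]]
      survived <- TRUE
    }
  }
  attr_mat <- NULL
  if (!is.null(attributes) && length(attr_rows) == length(sequences) &&
      length(attr_rows) > 0L)
    attr_mat <- do.call(rbind, attr_rows)
  structure(list(sequences = sequences, ids = ids,
                 attributes = attr_mat, stats = stats, config = cfg),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset: %d sequences%s>\n", length(x$sequences),
              if (is.null(x$attributes)) "" else
                sprintf(", %d attributes", ncol(x$attributes))))
  cat("  removals:", paste(names(x$stats), x$stats, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.gait_dataset <- function(x) length(x$sequences)
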