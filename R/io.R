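#' Write a pose-tracker stream document
#'
#' Serializes tracklets in the common pose-tracker JSON dialect: a flat
#' list of per-person records with an `image_id` frame number, a
#' `track_id`, a 54-float `keypoints` field (x, y, confidence triplets in
#' layout order) and a `box`. The raw dialect carries no frame rate, so
#' the fps is written to a `<path>.meta.json` sidecar.
#'
#' @param tracklets list of [gait_tracklet()] (all at the same fps).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(tracklets, path) {
  fps <- unique(vapply(tracklets, function(t) t$fps, numeric(1)))
  if (length(fps) != 1L) stop("all tracklets in a stream must share one fps")
  records <- list()
  for (tr in tracklets) {
    n <- dim(tr$data)[1L]
    kp <- flatten_sequence(gait_sequence(tr$data, ref_fps = tr$fps))
    for (t in seq_len(n)) {
      rec <- list(image_id = tr$frame_index[t], track_id = tr$track_id,
                  keypoints = unname(kp[t, ]))
      if (!is.null(tr$bbox)) rec$box <- unname(tr$bbox[t, ])
      records[[length(records) + 1L]] <- rec
    }
  }
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(fps = fps), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pose-tracker stream document
#'
#' Parses the pose-tracker JSON dialect written by [write_pose_stream()]
#' (and its common upstream variants): records are grouped by `track_id`
#' and ordered by frame index. Records with a malformed keypoint list are
#' skipped with a warning. The frame rate is taken from the `fps`
#' argument, a top-level `fps` field, or the `<path>.meta.json` sidecar —
#' in that order; a stream without any fps source is an error.
#'
#' @param path JSON path.
#' @param fps frame rate override.
#' @return List of [gait_tracklet()].
#' @export
read_pose_stream <- function(path, fps = NULL) {
  doc <- jsonlite::read_json(path)
  records <- doc
  if (!is.null(names(doc)) && "frames" %in% names(doc)) records <- doc$frames
  if (is.null(fps) && !is.null(names(doc)) && "fps" %in% names(doc))
    fps <- doc$fps
  sidecar <- paste0(path, ".meta.json")
  if (is.null(fps) && file.exists(sidecar))
    fps <- jsonlite::read_json(sidecar)$fps
  if (is.null(fps)) stop("no fps available for pose stream ", path)
  by_track <- list()
  for (rec in records) {
    kp <- unlist(rec$keypoints)
    if (length(kp) != TOKEN_DIM || any(!is.finite(kp))) {
      warning("skipping malformed pose record (keypoints must be 54 finite numbers)")
      next
    }
    id <- as.character(rec$track_id %||% rec$idx %||% "0")
    by_track[[id]] <- c(by_track[[id]], list(rec))
  }
  out <- list()
  for (id in names(by_track)) {
    recs <- by_track[[id]]
    fr <- vapply(recs, function(r) as.integer(r$image_id %||% 0L), integer(1))
    ord <- order(fr)
    recs <- recs[ord]; fr <- fr[ord]
    kp <- do.call(rbind, lapply(recs, function(r) unlist(r$keypoints)))
    dat <- unflatten_sequence(kp)$data
    bbox <- NULL
    if (!is.null(recs[[1L]]$box))
      bbox <- do.call(rbind, lapply(recs, function(r) unlist(r$box)))
    out[[length(out) + 1L]] <-
      gait_tracklet(dat, fps = fps, track_id = id, bbox = bbox,
                    frame_index = fr)
  }
  out
}

DATASET_FORMAT_VERSION <- 1L

#' Write a gait dataset archive
#'
#' Stores a [build_dataset()] corpus as a plain-text directory:
#' `meta.json` (format version, counts, pipeline config), `sequences.json`
#' (per-sequence token matrices), `ids.csv` and, when present,
#' `attributes.csv`. Everything is inspectable with standard tools;
#' `read_gait_dataset()` round-trips coordinates exactly (numbers are
#' written at full precision).
#'
#' @param dataset a `gait_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = DATASET_FORMAT_VERSION,
               n_sequences = length(dataset$sequences),
               ref_fps = if (length(dataset$sequences))
                 dataset$sequences[[1L]]$ref_fps else NA,
               stats = as.list(dataset$stats),
               config = unclass(dataset$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  seqs <- lapply(dataset$sequences, flatten_sequence)
  jsonlite::write_json(seqs, file.path(dir, "sequences.json"), digits = NA)
  utils::write.csv(data.frame(id = dataset$ids),
                   file.path(dir, "ids.csv"), row.names = FALSE)
  if (!is.null(dataset$attributes)) {
    df <- as.data.frame(dataset$attributes)
    df <- cbind(id = dataset$ids, df)
    utils::write.csv(df, file.path(dir, "attributes.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a gait dataset archive
#'
#' Inverse of [write_gait_dataset()]. A missing component or a format
#' version this package does not understand is an explicit error, never a
#' silent truncation.
#'
#' @param dir archive directory.
#' @return A `gait_dataset`.
#' @export
read_gait_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not a dataset archive (no meta.json): ", dir)
  meta <- jsonlite::read_json(meta_path)
  if (!identical(as.integer(meta$format_version), DATASET_FORMAT_VERSION))
    stop("dataset archive format version ", meta$format_version,
         " is not supported")
  seq_path <- file.path(dir, "sequences.json")
  ids_path <- file.path(dir, "ids.csv")
  if (!file.exists(seq_path) || !file.exists(ids_path))
    stop("corrupt dataset archive: missing sequences.json or ids.csv")
  raw <- jsonlite::read_json(seq_path, simplifyVector = FALSE)
  if (length(raw) != meta$n_sequences)
    stop("corrupt dataset archive: expected ", meta$n_sequences,
         " sequences, found ", length(raw))
  ref_fps <- meta$ref_fps %||% 24
  sequences <- lapply(raw, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) vapply(r, as.numeric, 0)))
    unflatten_sequence(m, ref_fps = ref_fps)
  })
  ids <- utils::read.csv(ids_path)$id
  attributes <- NULL
  attr_path <- file.path(dir, "attributes.csv")
  if (file.exists(attr_path)) {
    df <- utils::read.csv(attr_path, check.names = FALSE)
    attributes <- as.matrix(df[, -1L, drop = FALSE])
    rownames(attributes) <- df$id
  }
  cfg <- pipeline_config()
  if (!is.null(meta$config))
    cfg <- do.call(pipeline_config, meta$config[names(formals(pipeline_config))[
      names(formals(pipeline_config)) %in% names(meta$config)]])
  stats <- unlist(meta$stats)
  structure(list(sequences = sequences, ids = as.character(ids),
                 attributes = attributes,
                 stats = if (is.null(stats)) integer(0) else stats,
                 config = cfg),
            class = "gait_dataset")
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the full model object (config, weights, history), so
#' a loaded model is ready for prediction or continued training.
#'
#' @param model a [gait_transformer()].
#' @param path checkpoint path.
#' @return `path` invisibly, or the loaded model.
#' @export
save_gait_model <- function(model, path) {
  stopifnot(inherits(model, "gait_transformer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gait_model
#' @export
load_gait_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gait_transformer"))
    stop("not a gait_transformer checkpoint: ", path)
  model
}
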