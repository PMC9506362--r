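#' Load an attribute schema
#'
#' Reads the 42-attribute appearance schema: target attribute names, their
#' grouping into 8 categories (Gender, AgeGroup, BodyType, Viewpoint,
#' CarryConditions, Clothing, Footwear, ApparentAction), and the coalesce
#' map taking every source-network label either to a target attribute or to
#' an explicit `DROP`. The mapping is a shipped, user-overridable config so
#' that the label surgery is auditable rather than hard-coded.
#'
#' Validation happens here, at load time: any target named by the map but
#' absent from the groups, or vice versa, is a configuration error.
#'
#' @param path YAML schema file; defaults to the schema shipped with the
#'   package.
#' @return An object of class `attribute_schema` with components `names`
#'   (character(42)), `groups` (named character, attribute -> group),
#'   `modes` (named character, attribute -> "average"/"max") and `sources`
#'   (per-source named maps label -> target/DROP).
#' @export
attribute_schema <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "attribute_schema.yaml", package = "gaitseq")
  cfg <- yaml::read_yaml(path)
  groups <- cfg$groups
  names <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(names)) stop("schema: duplicated target attribute names")
  group_of <- stats::setNames(rep(names(groups), lengths(groups)), names)
  modes <- stats::setNames(rep(cfg$modes$default %||% "average", length(names)), names)
  for (a in setdiff(names(cfg$modes), "default")) {
    if (!a %in% names) stop("schema: mode given for unknown attribute ", a)
    modes[a] <- cfg$modes[[a]]
  }
  for (src in names(cfg$sources)) {
    tgt <- unlist(cfg$sources[[src]])
    bad <- setdiff(setdiff(tgt, "DROP"), names)
    if (length(bad))
      stop("schema: source '", src, "' maps to unknown target(s): ",
           paste(bad, collapse = ", "))
  }
  mapped <- setdiff(unique(unlist(lapply(cfg$sources, unlist))), "DROP")
  orphan <- setdiff(names, mapped)
  if (length(orphan))
    stop("schema: target(s) with no mapped source label: ",
         paste(orphan, collapse = ", "))
  structure(list(names = names, groups = group_of, modes = modes,
                 sources = lapply(cfg$sources, unlist),
                 version = cfg$version),
            class = "attribute_schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.attribute_schema <- function(x, ...) {
  cat(sprintf("<attribute_schema v%s: %d attributes in %d groups, %d sources>\n",
              x$version, length(x$names), length(unique(x$groups)),
              length(x$sources)))
  invisible(x)
}

#' Coalesce source-network predictions onto the target schema
#'
#' Each source network emits probabilities over its own label set; this maps
#' them onto the 42 target attributes. A target collects every mapped source
#' score and combines them by its configured mode: `average` (arithmetic
#' mean of scores measuring the same concept, e.g. two networks' child-age
#' labels) or `max` (union semantics over labels that partition a broader
#' concept, e.g. formal upper + formal lower + suit into formal wear).
#' `DROP`ped labels are ignored. A source label absent from the map is an
#' error; schemas are validated at load time, so this only fires for
#' mislabeled inputs.
#'
#' @param source_preds named list of named numeric vectors, one per source
#'   network (names must match `schema$sources`); each vector maps source
#'   labels to probabilities in `[0, 1]`. Sources may be missing.
#' @param schema an [attribute_schema()].
#' @return Named numeric vector of length 42 in `[0, 1]`; unobserved
#'   targets are 0.
#' @export
coalesce_attributes <- function(source_preds, schema = attribute_schema()) {
  vals <- stats::setNames(vector("list", length(schema$names)), schema$names)
  for (src in names(source_preds)) {
    map <- schema$sources[[src]]
    if (is.null(map)) stop("unknown source network: ", src)
    preds <- source_preds[[src]]
    unknown <- setdiff(names(preds), names(map))
    if (length(unknown))
      stop("source '", src, "' has unmapped label(s): ",
           paste(unknown, collapse = ", "))
    for (lab in names(preds)) {
      tgt <- map[[lab]]
      if (identical(tgt, "DROP")) next
      vals[[tgt]] <- c(vals[[tgt]], preds[[lab]])
    }
  }
  out <- stats::setNames(numeric(length(schema$names)), schema$names)
  for (a in schema$names) {
    if (length(vals[[a]]) == 0L) next
    out[a] <- if (schema$modes[[a]] == "max") max(vals[[a]]) else mean(vals[[a]])
  }
  out
}

#' Annotation configuration
#'
#' @param k_augment number of random augmentations averaged per crop.
#' @param period_T crop sampling stride in frames.
#' @param flip_p,rot_deg,jitter augmentation descriptors passed to the
#'   predictor's augmentation hook (horizontal flip probability, rotation
#'   range in degrees, brightness/contrast jitter fraction).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(k_augment = 4L, period_T = 48L,
                              flip_p = 0.5, rot_deg = 10, jitter = 0.2) {
  stopifnot(k_augment >= 1L)
  structure(list(k_augment = as.integer(k_augment),
                 period_T = as.integer(period_T),
                 flip_p = flip_p, rot_deg = rot_deg, jitter = jitter),
            class = "annotation_config")
}

#' Augmentation-averaged crop prediction
#'
#' Runs a pedestrian-attribute predictor on `k_augment` randomly augmented
#' copies of a crop and averages the per-label probabilities, making the
#' annotation robust to appearance noise. The predictor is an abstract
#' callable `function(crop, augment)` returning a named probability vector,
#' where `augment` is a descriptor list (`flip`, `rot_deg`, `jitter`) the
#' predictor may apply to the crop; deterministic mocks simply ignore it.
#' A copy on which the predictor fails is skipped; if all copies fail the
#' annotation of that crop is an error.
#'
#' @param predictor callable as described above.
#' @param crop the image crop (opaque to this package).
#' @param cfg an [annotation_config()].
#' @return Named numeric vector of per-label probabilities.
#' @export
predict_crop <- function(predictor, crop, cfg = annotation_config()) {
  preds <- list()
  for (k in seq_len(cfg$k_augment)) {
    aug <- list(flip = stats::runif(1) < cfg$flip_p,
                rot_deg = stats::runif(1, -cfg$rot_deg, cfg$rot_deg),
                jitter = stats::runif(1, -cfg$jitter, cfg$jitter))
    p <- tryCatch(predictor(crop, aug), error = function(e) NULL)
    if (!is.null(p)) preds[[length(preds) + 1L]] <- p
  }
  if (length(preds) == 0L) stop("predictor failed on all augmented copies")
  Reduce(`+`, preds) / length(preds)
}

#' Select annotation crops along a tracklet
#'
#' Takes the pedestrian crop at every `period_T` frames (frames 0, T, 2T,
#' ... in 0-based indexing), returning the frame indices and their bounding
#' boxes.
#'
#' @param track a [gait_tracklet()] with bounding boxes.
#' @param period_T sampling stride (default 48).
#' @return data.frame with columns `frame` (0-based index) and `x, y, w, h`.
#' @export
sample_crops <- function(track, period_T = 48L) {
  stopifnot(inherits(track, "gait_tracklet"))
  if (is.null(track$bbox)) stop("tracklet has no bounding boxes")
  n <- dim(track$data)[1L]
  sel <- seq.int(1L, n, by = period_T)
  data.frame(frame = sel - 1L,
             x = track$bbox[sel, 1L], y = track$bbox[sel, 2L],
             w = track$bbox[sel, 3L], h = track$bbox[sel, 4L])
}

#' Area-weighted sequence-level attribute aggregation
#'
#' Combines per-crop attribute vectors into one prediction for the whole
#' walking sequence, weighting each crop by its bounding-box area relative
#' to the image: larger crops (pedestrian closer to the camera) are more
#' clearly distinguishable and get higher weight.
#'
#' @param crop_preds list of equal-length numeric vectors (one per crop).
#' @param rel_areas non-negative relative areas, same length, not all zero.
#' @return Numeric vector: the convex combination with weights
#'   `rel_areas / sum(rel_areas)`.
#' @export
aggregate_tracklet <- function(crop_preds, rel_areas) {
  if (length(crop_preds) != length(rel_areas))
    stop("crop_preds and rel_areas must have equal length")
  if (any(rel_areas < 0)) stop("relative areas must be non-negative")
  s <- sum(rel_areas)
  if (s <= 0) stop("all relative areas are zero")
  w <- rel_areas / s
  Reduce(`+`, Map(`*`, crop_preds, w))
}

#' Annotate a tracklet with soft attribute labels
#'
#' Full annotation chain for one tracklet: sample crops every `period_T`
#' frames, run each source predictor with augmentation averaging, coalesce
#' onto the 42-attribute schema and aggregate over crops with bbox-area
#' weights. Labels stay soft (probabilities are never rounded), which keeps
#' the downstream distillation robust to annotation noise.
#'
#' @param track a [gait_tracklet()] with bounding boxes.
#' @param predictors named list of predictor callables, names matching the
#'   schema's sources; each is called as `predictor(crop, augment)` where
#'   `crop` is the `(frame, bbox)` descriptor row.
#' @param schema an [attribute_schema()].
#' @param cfg an [annotation_config()].
#' @param frame_area image area in px^2 used for relative bbox area; when
#'   `NULL`, areas are normalized by the largest sampled bbox.
#' @return Named numeric vector of 42 soft labels in `[0, 1]`.
#' @export
annotate_tracklet <- function(track, predictors, schema = attribute_schema(),
                              cfg = annotation_config(), frame_area = NULL) {
  crops <- sample_crops(track, cfg$period_T)
  areas <- crops$w * crops$h
  rel <- if (is.null(frame_area)) areas / max(areas) else areas / frame_area
  preds <- vector("list", nrow(crops))
  for (i in seq_len(nrow(crops))) {
    per_source <- lapply(predictors, function(pr) predict_crop(pr, crops[i, ], cfg))
    preds[[i]] <- coalesce_attributes(per_source, schema)
  }
  out <- aggregate_tracklet(preds, rel)
  pmin(pmax(out, 0), 1)
}
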