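#' Sample a synthetic walker identity
#'
#' Draws the latent kinematic parameters of one synthetic walking identity
#' and derives its 42 soft attribute labels through a fixed, documented
#' monotone map. The walker model is a test harness that emulates the
#' statistical structure pose-tracker corpora provide — periodic limb
#' kinematics, identity-specific parameters, correlation between movement
#' and a subset of appearance attributes — not a biomechanical simulator.
#'
#' Movement-coded attributes (see [coded_attributes()]): stride amplitude
#' and the arm-swing/stride ratio drive the age-group scores, the
#' hip/shoulder width ratio drives the body-type scores (the ratio survives
#' normalization), the camera azimuth drives the viewpoint scores (via
#' lateral-amplitude inflation, head lead and face-joint confidences), and
#' a hip-ratio + arm-swing combination drives the gender scores. All of
#' these cues survive both the normalization and the training-time
#' augmentation suite; absolute cadence deliberately carries no attribute
#' information because random pace augmentation makes learned
#' representations cadence-invariant. The remaining clothing / carry /
#' action attributes get weak identity-specific noise so that, as with
#' real ensembles, some labels are simply not recoverable from movement.
#'
#' @param seed integer seed; the walker is deterministic given the seed.
#' @return List with `params` (named list of class `walker_params`) and
#'   `attributes` (named numeric(42) in `[0, 1]`).
#' @export
sample_walker <- function(seed) {
  set.seed(seed)
  p <- list(
    seed = as.integer(seed),
    freq = stats::runif(1, 0.7, 1.3),            # gait cycles per second
    stride = stats::runif(1, 0.10, 0.22),        # base normalized ankle amplitude
    arm_ratio = stats::runif(1, 0.25, 0.55),     # arm swing relative to stride
    torso = stats::runif(1, 70, 95),             # neck-pelvis distance, px
    shoulder = stats::runif(1, 32, 48),          # frontal shoulder span, px
    hip_ratio = stats::runif(1, 0.55, 0.95),     # hip span / shoulder span
    leg_ratio = stats::runif(1, 1.05, 1.25),     # leg length / torso
    phase = stats::runif(1, 0, 2 * pi),
    view = stats::runif(1, 0, pi),               # azimuth: 0 front, pi/2 side, pi back
    bob = stats::runif(1, 0.015, 0.035),         # pelvis bob, torso units
    noise_px = stats::runif(1, 0.1, 0.4),        # per-joint tracker jitter, px
    conf_shape1 = 46, conf_shape2 = 4            # Beta -> confidences near 0.92
  )
  class(p) <- "walker_params"
  list(params = p, attributes = walker_attributes(p))
}

#' Movement-coded attribute names
#'
#' The attributes whose synthetic soft labels are driven by the walker's
#' kinematic parameters (`strong`) versus assigned weak identity noise
#' (`weak`). Only the strong set is recoverable from movement by
#' construction.
#'
#' @param schema an [attribute_schema()].
#' @return List with character vectors `strong` and `weak`.
#' @export
coded_attributes <- function(schema = attribute_schema()) {
  strong <- names(schema$groups)[schema$groups %in%
                                   c("Gender", "AgeGroup", "BodyType", "Viewpoint")]
  list(strong = strong, weak = setdiff(schema$names, strong))
}

# Deterministic monotone map from kinematic parameters to soft labels.
# Only pace-invariant movement features feed the map: the training-time
# augmentation suite includes random pace changes, so a representation
# learned by the method is cadence-invariant by design and absolute gait
# frequency cannot carry attribute information. Stride amplitude, the
# arm-swing/stride ratio and the hip/shoulder ratio all survive both the
# pace augmentation and the normalization.
walker_attributes <- function(p, schema = attribute_schema()) {
  u_a <- (p$stride - 0.10) / 0.12          # stride amplitude, 0..1
  u_arm <- (p$arm_ratio - 0.25) / 0.30     # arm swing relative to stride, 0..1
  u_h <- (p$hip_ratio - 0.55) / 0.40       # hip/shoulder ratio, 0..1
  u_v <- p$view / pi                       # azimuth, 0..1
  # ordinal cumulative coding: every label is a logistic threshold on a
  # latent, hence monotone in the underlying parameters
  thr <- function(x, center, width = 0.12) stats::plogis((x - center) / width)
  out <- stats::setNames(numeric(length(schema$names)), schema$names)
  female <- stats::plogis(2.2 * (2 * u_h - 1) + 0.8 * (2 * u_arm - 1))
  out["Female"] <- female
  out["Male"] <- 1 - female
  age <- 0.55 * (1 - u_arm) + 0.45 * (1 - u_a)  # smaller swing & stride = older
  out["AgeChild"] <- thr(0.25, age)        # well below the adult band
  out["AgeYoungAdult"] <- thr(0.50, age)   # below the middle of the range
  out["AgeAdult"] <- thr(age, 0.50)
  out["AgeElderly"] <- thr(age, 0.75)
  out["BodyThin"] <- thr(0.33, u_h)
  out["BodyNormal"] <- thr(0.66, u_h)      # "not heavy-set"
  out["BodyFat"] <- thr(u_h, 0.66)
  out["Front"] <- thr(0.40, u_v, 0.10)
  out["Side"] <- thr(sin(p$view), 0.75)    # monotone in the lateral exposure
  out["Back"] <- thr(u_v, 0.60, 0.10)
  weak <- coded_attributes(schema)$weak
  out[weak] <- pmin(pmax(0.15 + stats::runif(length(weak), -0.12, 0.35), 0), 1)
  out
}

# view-dependent geometry shared by the renderer and its calibration:
# lateral amplitudes shrink toward frontal/back views while the apparent
# shoulder span shrinks toward the side view, so normalized amplitudes
# inflate laterally -- the cue that codes the viewpoint.
view_factors <- function(view) {
  list(lat = 0.4 + 0.6 * sin(view),
       sh = 0.55 + 0.45 * abs(cos(view)))
}

#' Render a tracker-style tracklet for a walker
#'
#' Generates the 18-joint planar kinematics of a walking person as coupled
#' sinusoids — legs in anti-phase at the gait frequency, arms
#' counter-phased with the ipsilateral leg, pelvis bobbing at twice the
#' stride rate — plus per-joint tracker jitter, Beta-distributed
#' confidences concentrated near 0.92 (face-joint confidences drop for
#' back views, as a tracker's would), and bounding boxes from the joint
#' extents. A nominal render passes every corpus filter.
#'
#' @param params a `walker_params` list from [sample_walker()].
#' @param n_frames number of frames (>= 2).
#' @param fps stream frame rate.
#' @param seed optional seed for the render's noise draws.
#' @param track_id identifier for the resulting tracklet.
#' @return A [gait_tracklet()] with bounding boxes.
#' @export
render_tracklet <- function(params, n_frames = 144L, fps = 24,
                            seed = NULL, track_id = NULL) {
  stopifnot(inherits(params, "walker_params"), n_frames >= 2L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(track_id)) track_id <- sprintf("walker%08d", params$seed)
  lay <- joint_layout()
  vf <- view_factors(params$view)
  w <- params$shoulder * vf$sh                  # apparent shoulder span, px
  h <- params$torso
  leg <- params$leg_ratio * h
  amp <- params$stride * vf$lat / vf$sh * w     # ankle x amplitude, px
  arm_amp <- params$arm_ratio * amp
  hipw <- params$hip_ratio * w
  tt <- (seq_len(n_frames) - 1) / fps
  ph <- 2 * pi * params$freq * tt + params$phase
  cx <- 320; cy <- 260                          # scene position, removed by normalization
  dat <- array(0, c(n_frames, N_JOINTS, 3L))
  X <- matrix(0, n_frames, N_JOINTS); Y <- matrix(0, n_frames, N_JOINTS)
  pel_y <- cy + params$bob * h * sin(2 * ph)
  # hips
  X[, lay$l_hip] <- cx - hipw / 2; X[, lay$r_hip] <- cx + hipw / 2
  Y[, lay$l_hip] <- pel_y;         Y[, lay$r_hip] <- pel_y
  # torso and head
  X[, lay$neck] <- cx;             Y[, lay$neck] <- pel_y - h
  X[, lay$l_shoulder] <- cx - w / 2; X[, lay$r_shoulder] <- cx + w / 2
  Y[, lay$l_shoulder] <- pel_y - h;  Y[, lay$r_shoulder] <- pel_y - h
  # head: leads in the walking direction with azimuth, giving a clean
  # geometric viewpoint cue on top of the amplitude inflation
  lean <- 0.25 * w * sin(params$view)
  X[, 1L] <- cx + lean;            Y[, 1L] <- pel_y - 1.22 * h   # nose
  X[, 15L] <- cx + lean + 0.06 * w; Y[, 15L] <- pel_y - 1.25 * h # eyes
  X[, 16L] <- cx + lean - 0.06 * w; Y[, 16L] <- pel_y - 1.25 * h
  X[, 17L] <- cx + lean + 0.10 * w; Y[, 17L] <- pel_y - 1.20 * h # ears
  X[, 18L] <- cx + lean - 0.10 * w; Y[, 18L] <- pel_y - 1.20 * h
  # legs: left at phase ph, right in anti-phase; knees carry half the swing
  lift <- 0.05 * leg
  for (side in c("l", "r")) {
    hip_i <- if (side == "l") lay$l_hip else lay$r_hip
    knee_i <- if (side == "l") 13L else 10L
    ankle_i <- if (side == "l") 14L else 11L
    phs <- if (side == "l") ph else ph + pi
    X[, knee_i] <- X[, hip_i] + 0.5 * amp * sin(phs)
    Y[, knee_i] <- pel_y + 0.5 * leg - 0.5 * lift * pmax(0, sin(phs))
    X[, ankle_i] <- X[, hip_i] + amp * sin(phs)
    Y[, ankle_i] <- pel_y + leg - lift * pmax(0, sin(phs))
  }
  # arms: counter-phase with the ipsilateral leg
  for (side in c("l", "r")) {
    sh_i <- if (side == "l") lay$l_shoulder else lay$r_shoulder
    elb_i <- if (side == "l") 7L else 4L
    wr_i <- if (side == "l") 8L else 5L
    phs <- if (side == "l") ph + pi else ph
    X[, elb_i] <- X[, sh_i] + 0.5 * arm_amp * sin(phs)
    Y[, elb_i] <- pel_y - 0.55 * h
    X[, wr_i] <- X[, sh_i] + arm_amp * sin(phs)
    Y[, wr_i] <- pel_y - 0.15 * h
  }
  X <- X + matrix(stats::rnorm(n_frames * N_JOINTS, 0, params$noise_px),
                  n_frames, N_JOINTS)
  Y <- Y + matrix(stats::rnorm(n_frames * N_JOINTS, 0, params$noise_px),
                  n_frames, N_JOINTS)
  conf <- matrix(stats::rbeta(n_frames * N_JOINTS, params$conf_shape1,
                              params$conf_shape2), n_frames, N_JOINTS)
  if (params$view > pi / 2) {                   # face joints unreliable from behind
    face <- c(1L, 15L, 16L, 17L, 18L)
    conf[, face] <- stats::rbeta(n_frames * length(face), 4, 14)
  }
  dat[, , 1L] <- X; dat[, , 2L] <- Y; dat[, , 3L] <- conf
  xmin <- apply(X, 1L, min); xmax <- apply(X, 1L, max)
  ymin <- apply(Y, 1L, min); ymax <- apply(Y, 1L, max)
  bbox <- cbind(xmin - 2, ymin - 2, xmax - xmin + 4, ymax - ymin + 4)
  gait_tracklet(dat, fps = fps, track_id = track_id, bbox = bbox)
}

#' Generate a pretraining corpus of synthetic walkers
#'
#' One tracklet per identity (a tracklet is treated as a unique identity
#' downstream), with the walker's soft attribute labels attached. All
#' randomness derives from `seed`.
#'
#' @param n_ids number of identities (>= 2).
#' @param frames_per_id frames per tracklet.
#' @param fps stream frame rate.
#' @param seed master seed.
#' @return An object of class `gait_corpus`: list with `tracklets`,
#'   `params`, `attributes` (matrix `n_ids x 42` with tracklet-id
#'   rownames) and `ids`.
#' @export
make_pretraining_corpus <- function(n_ids, frames_per_id = 144L, fps = 24,
                                    seed = 1L) {
  stopifnot(n_ids >= 2L)
  set.seed(seed)
  walker_seeds <- sample.int(2^30, n_ids)
  render_seeds <- sample.int(2^30, n_ids)
  tracklets <- vector("list", n_ids)
  params <- vector("list", n_ids)
  attrs <- NULL
  ids <- sprintf("id%04d", seq_len(n_ids))
  for (i in seq_len(n_ids)) {
    wk <- sample_walker(walker_seeds[i])
    params[[i]] <- wk$params
    attrs <- rbind(attrs, wk$attributes)
    tracklets[[i]] <- render_tracklet(wk$params, frames_per_id, fps,
                                      seed = render_seeds[i], track_id = ids[i])
  }
  rownames(attrs) <- ids
  structure(list(tracklets = tracklets, params = params,
                 attributes = attrs, ids = ids, seed = seed),
            class = "gait_corpus")
}

#' @export
print.gait_corpus <- function(x, ...) {
  cat(sprintf("<gait_corpus: %d synthetic walkers, %d frames each>\n",
              length(x$tracklets), dim(x$tracklets[[1]]$data)[1L]))
  invisible(x)
}

#' Build a gait_dataset from a synthetic corpus
#'
#' Convenience wrapper running [build_dataset()] with the corpus'
#' attribute rows attached to the survivors.
#'
#' @param corpus a [make_pretraining_corpus()] result.
#' @param cfg a [pipeline_config()].
#' @return A `gait_dataset`.
#' @export
corpus_dataset <- function(corpus, cfg = pipeline_config()) {
  stopifnot(inherits(corpus, "gait_corpus"))
  attr_list <- stats::setNames(
    lapply(seq_len(nrow(corpus$attributes)),
           function(i) corpus$attributes[i, ]),
    rownames(corpus$attributes))
  build_dataset(corpus$tracklets, cfg, attributes = attr_list)
}

#' Planted-defect filter fixture
#'
#' Constructs a mixed bag of tracklets where each defect class violates
#' exactly one corpus filter: `too_short` fails the duration filter,
#' `low_conf` has all frames below the mean-confidence threshold,
#' `low_feet_conf` has confident bodies but unreliable ankles, `static`
#' stands still (leg speed below the band) and `erratic` jumps wildly
#' (above the band). `nominal` tracklets pass everything, so the expected
#' number of [build_dataset()] survivors equals the nominal count.
#'
#' @param spec named counts over
#'   `nominal, too_short, low_conf, low_feet_conf, static, erratic`
#'   (missing classes default to 0).
#' @param seed master seed.
#' @param fps stream frame rate for all tracklets.
#' @return List with `tracklets` (shuffled), `expected_survivors` and
#'   `classes` (the class of each tracklet, aligned).
#' @export
make_filter_fixture <- function(spec, seed = 1L, fps = 24) {
  classes <- c("nominal", "too_short", "low_conf", "low_feet_conf",
               "static", "erratic")
  counts <- stats::setNames(rep(0L, length(classes)), classes)
  counts[names(spec)] <- as.integer(spec)
  set.seed(seed)
  tracklets <- list(); labels <- character(0)
  k <- 0L
  for (cls in classes) {
    for (j in seq_len(counts[[cls]])) {
      k <- k + 1L
      wseed <- sample.int(2^30, 1L); rseed <- sample.int(2^30, 1L)
      wk <- sample_walker(wseed)
      id <- sprintf("%s%03d", cls, j)
      tr <- switch(cls,
        nominal = render_tracklet(wk$params, 144L, fps, rseed, id),
        too_short = render_tracklet(wk$params, 30L, fps, rseed, id),
        low_conf = {
          t0 <- render_tracklet(wk$params, 144L, fps, rseed, id)
          n <- dim(t0$data)[1L]
          t0$data[, , 3L] <- matrix(stats::rbeta(n * N_JOINTS, 5, 12), n)
          t0
        },
        low_feet_conf = {
          t0 <- render_tracklet(wk$params, 144L, fps, rseed, id)
          lay <- joint_layout()
          n <- dim(t0$data)[1L]
          t0$data[, lay$feet, 3L] <- matrix(stats::rbeta(n * 2L, 4, 16), n)
          t0
        },
        static = {
          # freeze the gait cycle entirely: a standing person
          p <- wk$params; p$freq <- 0; p$bob <- 0; p$noise_px <- 0
          render_tracklet(p, 144L, fps, rseed, id)
        },
        erratic = {
          p <- wk$params; p$noise_px <- 30
          render_tracklet(p, 144L, fps, rseed, id)
        })
      tracklets[[k]] <- tr; labels[k] <- cls
    }
  }
  if (k > 1L) {
    ord <- sample.int(k)
    tracklets <- tracklets[ord]; labels <- labels[ord]
  }
  list(tracklets = tracklets,
       expected_survivors = counts[["nominal"]],
       classes = labels)
}
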