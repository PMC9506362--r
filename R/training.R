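#' Training configuration
#'
#' Hyper-parameters of the contrastive / multi-task training loop. The
#' defaults are the large-corpus pretraining settings: supervised
#' contrastive temperature `tau = 0.001`, appearance-loss weight
#' `lambda_app = 0.5` (chosen so the two losses have similar magnitude),
#' a batch of 1024 view-samples (512 tracklets times two views), a
#' triangular cyclical learning rate sweeping 1e-4 to 1e-3 over 20-epoch
#' cycles, and 400 epochs. Fine-tuning uses a linear 1e-4 -> 0 schedule
#' over 200 epochs with layer-wise learning-rate decay 0.9.
#'
#' @param tau contrastive temperature (> 0).
#' @param lambda_app appearance-loss weight.
#' @param batch_size number of view-samples per step (two views per
#'   tracklet, so `batch_size / 2` tracklets).
#' @param epochs pretraining epochs.
#' @param lr_lo,lr_hi cyclical learning-rate endpoints.
#' @param lr_cycle_epochs epochs per full triangular cycle.
#' @param finetune_epochs,finetune_lr0 fine-tuning schedule.
#' @param llrd_decay layer-wise learning-rate decay factor.
#' @param clip_norm global gradient-norm clip (sharp temperatures scale
#'   contrastive gradients by `1/tau`; clipping keeps the update bounded).
#'   `Inf` disables.
#' @param seed RNG seed used by the training loop.
#' @return A list of class `training_config`.
#' @export
training_config <- function(tau = 0.001, lambda_app = 0.5, batch_size = 1024L,
                            epochs = 400L, lr_lo = 1e-4, lr_hi = 1e-3,
                            lr_cycle_epochs = 20L, finetune_epochs = 200L,
                            finetune_lr0 = 1e-4, llrd_decay = 0.9,
                            clip_norm = 1.0, seed = 1L) {
  stopifnot(tau > 0, lambda_app >= 0, lr_lo < lr_hi)
  structure(list(tau = tau, lambda_app = lambda_app,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr_lo = lr_lo, lr_hi = lr_hi,
                 lr_cycle_epochs = as.integer(lr_cycle_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 finetune_lr0 = finetune_lr0, llrd_decay = llrd_decay,
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "training_config")
}

l2_normalize_rows <- function(x, eps = 1e-12) {
  x / pmax(sqrt(rowSums(x * x)), eps)
}

#' Supervised contrastive loss
#'
#' Multi-view batch contrastive loss: for each anchor `i`, every other
#' sample with the same label is a positive, and the loss averages
#' `-log( exp(z_i . z_p / tau) / sum_a exp(z_i . z_a / tau) )` over the
#' positive set, then over anchors. Projections are l2-normalized before
#' the dot products, and the log-sum-exp is computed with max subtraction
#' so sharp temperatures (`tau = 0.001` scales similarities by 1000) stay
#' finite.
#'
#' Every sample must have at least one positive — the two-view sampler
#' guarantees this; a violation is an error, not a silent skip.
#'
#' @param projections numeric `n x d` matrix (raw projections; normalized
#'   internally).
#' @param labels vector of length `n`; equal labels mark positives.
#' @param tau temperature.
#' @param grad also return the gradient with respect to the raw
#'   projections.
#' @return The loss (scalar), or if `grad = TRUE` a list `(loss, grad)`.
#' @export
supcon_loss <- function(projections, labels, tau = 0.001, grad = FALSE) {
  Z0 <- as.matrix(projections)
  n <- nrow(Z0)
  if (n < 2L) stop("contrastive loss needs at least 2 samples")
  if (length(labels) != n) stop("labels must match the number of projections")
  r <- pmax(sqrt(rowSums(Z0 * Z0)), 1e-12)
  Z <- Z0 / r
  S <- tcrossprod(Z) / tau
  diag(S) <- -Inf
  rmax <- apply(S, 1L, max)
  E <- exp(S - rmax)
  diag(E) <- 0
  denom <- rowSums(E)
  logprob <- S - rmax - log(denom)
  pos <- outer(labels, labels, `==`)
  diag(pos) <- FALSE
  counts <- rowSums(pos)
  if (any(counts == 0L))
    stop("every sample needs at least one positive (two-view sampler contract)")
  loss_i <- -rowSums(ifelse(pos, logprob, 0)) / counts
  loss <- mean(loss_i)
  if (!grad) return(loss)
  soft <- E / denom
  G <- (soft - pos / counts) / n
  diag(G) <- 0
  dZ <- (G + t(G)) %*% Z / tau
  dZ0 <- (dZ - Z * rowSums(Z * dZ)) / r
  list(loss = loss, grad = dZ0)
}

#' Soft-label binary cross-entropy
#'
#' Mean over all entries of `-(y log p + (1 - y) log(1 - p))` with
#' probability-valued (soft) targets `y`; predictions are clamped to
#' `[1e-7, 1 - 1e-7]`. With soft targets the minimum over `p` sits at
#' `p = y`, which is what makes the attribute head a distillation of the
#' annotating ensemble rather than a hard classifier.
#'
#' @param pred predicted probabilities (any shape).
#' @param target soft labels in `[0, 1]`, same shape.
#' @return Scalar mean loss.
#' @export
soft_bce <- function(pred, target) {
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Combined multi-task loss
#'
#' `l_supcon + lambda_app * l_appearance`.
#'
#' @param l_supcon contrastive loss value.
#' @param l_appearance appearance (soft BCE) loss value.
#' @param lambda_app weight on the appearance term.
#' @return Scalar.
#' @export
combined_loss <- function(l_supcon, l_appearance, lambda_app = 0.5) {
  l_supcon + lambda_app * l_appearance
}

#' Triangular cyclical learning rate
#'
#' `lr_lo` at the start and end of each cycle, `lr_hi` at mid-cycle,
#' linear in between, period `lr_cycle_epochs`.
#'
#' @param epoch epoch index (0-based; may be fractional).
#' @param cfg a [training_config()].
#' @return Learning rate.
#' @export
cyclical_lr <- function(epoch, cfg = training_config()) {
  cycle <- cfg$lr_cycle_epochs
  pos <- epoch %% cycle
  half <- cycle / 2
  frac <- ifelse(pos <= half, pos / half, (cycle - pos) / half)
  cfg$lr_lo + (cfg$lr_hi - cfg$lr_lo) * frac
}

#' Linear decay learning rate
#'
#' Decreases linearly from `lr0` at epoch 0 to 0 at `total` epochs — the
#' fine-tuning schedule.
#'
#' @param epoch epoch index (0-based).
#' @param lr0 initial rate.
#' @param total number of epochs to reach zero.
#' @return Learning rate (never negative).
#' @export
linear_lr <- function(epoch, lr0 = 1e-4, total = 200L) {
  pmax(lr0 * (1 - epoch / total), 0)
}

#' Layer-wise learning-rate decay groups
#'
#' Assigns a per-parameter learning rate for fine-tuning: the heads
#' (embedding, contrastive, appearance and any task head) train at `lr0`,
#' encoder layers get geometrically smaller rates with depth from the top
#' (`lr0 * decay` for the top layer down to `lr0 * decay^L` for the
#' bottom), and the input projection and positional table get the smallest
#' rate, `lr0 * decay^(L + 1)`.
#'
#' @param model a [gait_transformer()].
#' @param lr0 head learning rate.
#' @param decay decay factor in `(0, 1]`.
#' @return Named numeric vector: learning rate per parameter tensor.
#' @export
llrd_param_groups <- function(model, lr0 = 1e-4, decay = 0.9) {
  stopifnot(inherits(model, "gait_transformer"))
  L <- model$config$n_layers
  nm <- names(model$params)
  rate <- stats::setNames(rep(lr0, length(nm)), nm)
  for (l in seq_len(L)) {
    depth_from_top <- L - l + 1L
    rate[startsWith(nm, sprintf("enc%d.", l))] <- lr0 * decay^depth_from_top
  }
  rate[nm %in% c("proj.W", "proj.b", "pos")] <- lr0 * decay^(L + 1L)
  rate
}

# ---- Adam with optional per-parameter rates and global-norm clipping ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, clip_norm = Inf,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.finite(clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (gn > clip_norm) grads <- lapply(grads, function(g) g * (clip_norm / gn))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  if (length(lr) == 1L) lr <- stats::setNames(rep(lr, length(params)), names(params))
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Assemble a two-view batch from dataset rows `take`: 2N x T x 54 tokens,
# labels rep(ids, 2), plus row indices for attribute lookup.
make_view_batch <- function(dataset, take, aug_cfg) {
  T <- aug_cfg$crop_T
  n <- length(take)
  tokens <- array(0, c(2L * n, T, TOKEN_DIM))
  for (j in seq_along(take)) {
    vs <- two_views(dataset$sequences[[take[j]]], aug_cfg)
    tokens[j, , ] <- flatten_sequence(vs[[1L]])
    tokens[n + j, , ] <- flatten_sequence(vs[[2L]])
  }
  list(tokens = tokens,
       labels = rep(dataset$ids[take], 2L),
       rows = rep(take, 2L))
}

#' Pretrain a gait transformer on a corpus
#'
#' The package's central fitting function. Trains a pose-token transformer
#' on a [build_dataset()] corpus where every tracklet is its own identity:
#' each step samples tracklets, draws two augmented views of each
#' ([two_views()]), and minimizes the supervised contrastive loss over the
#' 128-d projections — in `"multitask"` mode plus `lambda_app` times the
#' soft binary cross-entropy between the appearance head and the
#' tracklet's soft attribute labels (computed on both views). Optimization
#' is Adam under the triangular cyclical learning rate, with global
#' gradient-norm clipping.
#'
#' In `"contrastive"` mode the appearance head receives no gradient and
#' its weights remain bit-identical to their initialization.
#'
#' @param dataset a `gait_dataset`; must carry attributes for
#'   `mode = "multitask"`.
#' @param model a [model_config()] or an already-built/pretrained
#'   [gait_transformer()] to continue from.
#' @param training a [training_config()].
#' @param mode `"contrastive"` or `"multitask"`.
#' @param augment an [augment_config()].
#' @param verbose print a line every 10 epochs.
#' @return A fitted `gait_transformer` whose `history` is a data.frame
#'   with per-epoch `loss` (combined), `loss_supcon`, `loss_app` and `lr`,
#'   and with `mode` recorded.
#' @seealso [predict.gait_transformer()], [gait_finetune()]
#' @export
gait_pretrain <- function(dataset, model = model_config(),
                          training = training_config(),
                          mode = c("multitask", "contrastive"),
                          augment = augment_config(), verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "gait_dataset"))
  if (length(dataset$sequences) == 0L) stop("dataset is empty")
  if (mode == "multitask" && is.null(dataset$attributes))
    stop("multitask pretraining needs a dataset with attributes")
  set.seed(training$seed)
  if (inherits(model, "model_config")) {
    if (mode == "multitask" && model$n_attributes != ncol(dataset$attributes))
      stop("model n_attributes does not match the dataset attribute count")
    model <- gait_transformer(model)
  }
  n_track <- length(dataset$sequences)
  n_per_step <- max(2L, min(training$batch_size %/% 2L, n_track))
  steps <- max(1L, n_track %/% n_per_step)
  opt <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     loss_supcon = numeric(0), loss_app = numeric(0),
                     lr = numeric(0))
  for (epoch in seq_len(training$epochs)) {
    lr <- cyclical_lr(epoch - 1L, training)
    ep_sup <- 0; ep_app <- 0
    for (s in seq_len(steps)) {
      take <- if (n_per_step == n_track) seq_len(n_track)
              else sample.int(n_track, n_per_step)
      batch <- make_view_batch(dataset, take, augment)
      fw <- gait_forward(model, batch$tokens, cache = TRUE)
      sc <- supcon_loss(fw$projection, batch$labels, training$tau, grad = TRUE)
      d_out <- list(d_proj = sc$grad)
      l_app <- NA_real_
      if (mode == "multitask") {
        y <- dataset$attributes[batch$rows, , drop = FALSE]
        p <- fw$attributes
        l_app <- soft_bce(p, y)
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        d_out$d_attr_logits <- training$lambda_app * (pc - y) / length(y)
      }
      grads <- gait_backward(model, fw$cache, d_out)
      upd <- adam_step(model$params, grads, opt, lr, training$clip_norm)
      model$params <- upd$params; opt <- upd$state
      ep_sup <- ep_sup + sc$loss
      ep_app <- ep_app + if (is.na(l_app)) 0 else l_app
    }
    ep_sup <- ep_sup / steps; ep_app <- ep_app / steps
    total <- if (mode == "multitask")
      combined_loss(ep_sup, ep_app, training$lambda_app) else ep_sup
    hist[nrow(hist) + 1L, ] <- list(epoch, total, ep_sup,
                                    if (mode == "multitask") ep_app else NA_real_,
                                    lr)
    if (verbose && epoch %% 10L == 0L)
      message(sprintf("epoch %d: loss %.4f (supcon %.4f) lr %.2g",
                      epoch, total, ep_sup, lr))
  }
  model$history <- hist
  model$mode <- mode
  model$attr_names <- colnames(dataset$attributes)
  model
}

#' Fine-tune a pretrained gait transformer
#'
#' Adapts a pretrained model to a labelled downstream task with layer-wise
#' learning-rate decay ([llrd_param_groups()]) and a linear
#' `finetune_lr0 -> 0` schedule over `finetune_epochs`:
#' \describe{
#'   \item{`"recognition"`}{supervised contrastive loss with the subject id
#'     as the class; positives are other sequences (and views) of the same
#'     subject.}
#'   \item{`"gender"`}{binary cross-entropy on a scalar sigmoid head
#'     (added on first use) against 0/1 labels.}
#' }
#'
#' @param model a pretrained [gait_transformer()].
#' @param sequences list of [gait_sequence()], each at least `crop_T` long.
#' @param labels per-sequence labels: subject ids for recognition, 0/1 for
#'   gender.
#' @param task `"recognition"` or `"gender"`.
#' @param training a [training_config()] (uses the `finetune_*` and
#'   `llrd_decay` fields).
#' @param augment an [augment_config()].
#' @return The fine-tuned model; `history` holds the per-epoch task loss.
#' @export
gait_finetune <- function(model, sequences, labels,
                          task = c("recognition", "gender"),
                          training = training_config(),
                          augment = augment_config()) {
  task <- match.arg(task)
  stopifnot(inherits(model, "gait_transformer"))
  if (length(sequences) != length(labels))
    stop("labels must match sequences")
  set.seed(training$seed)
  if (task == "gender") {
    labels <- as.numeric(labels)
    if (!all(labels %in% c(0, 1))) stop("gender labels must be 0/1")
    if (is.null(model$params$head.gender.W)) {
      model$params$head.gender.W <- glorot(model$config$emb_dim, 1L)
      model$params$head.gender.b <- numeric(1L)
    }
  }
  rates <- llrd_param_groups(model, training$finetune_lr0, training$llrd_decay)
  opt <- adam_init(model$params)
  n <- length(sequences)
  n_per_step <- max(2L, min(training$batch_size %/% 2L, n))
  hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(training$finetune_epochs)) {
    fac <- linear_lr(epoch - 1L, 1, training$finetune_epochs)
    lr <- rates * fac
    take <- if (n_per_step >= n) seq_len(n) else sample.int(n, n_per_step)
    if (task == "recognition") {
      ds <- structure(list(sequences = sequences, ids = as.character(labels)),
                      class = "gait_dataset")
      batch <- make_view_batch(ds, take, augment)
      fw <- gait_forward(model, batch$tokens, cache = TRUE)
      sc <- supcon_loss(fw$projection, batch$labels, training$tau, grad = TRUE)
      loss <- sc$loss
      grads <- gait_backward(model, fw$cache, list(d_proj = sc$grad))
    } else {
      T <- augment$crop_T
      tokens <- array(0, c(length(take), T, TOKEN_DIM))
      for (j in seq_along(take))
        tokens[j, , ] <- flatten_sequence(
          augment_once(sequences[[take[j]]], augment))
      y <- labels[take]
      fw <- gait_forward(model, tokens, cache = TRUE)
      logit <- fw$embedding %*% model$params$head.gender.W +
        model$params$head.gender.b[1L]
      prob <- 1 / (1 + exp(-logit))
      loss <- soft_bce(prob, y)
      d_logit <- (pmin(pmax(prob, 1e-7), 1 - 1e-7) - y) / length(y)
      d_emb <- d_logit %*% t(model$params$head.gender.W)
      grads <- gait_backward(model, fw$cache, list(d_emb = d_emb))
      grads$head.gender.W <- crossprod(fw$cache$emb, d_logit)
      grads$head.gender.b <- sum(d_logit)
      grads <- grads[names(model$params)]
    }
    upd <- adam_step(model$params, grads, opt, lr, training$clip_norm)
    model$params <- upd$params; opt <- upd$state
    hist[nrow(hist) + 1L, ] <- list(epoch, loss, fac * training$finetune_lr0)
  }
  model$history <- hist
  model$task <- task
  model
}
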