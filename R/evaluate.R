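#' Extract identity embeddings
#'
#' The deterministic evaluation path: center crop of `T` frames, forward
#' pass, 256-d embedding, l2 normalization. No test-time augmentation.
#'
#' @param model a [gait_transformer()].
#' @param sequences list of [gait_sequence()], each of length `>= T`.
#' @param T evaluation crop length (default 48).
#' @param batch_size forward-pass chunk size.
#' @return Numeric `N x emb_dim` matrix of unit-norm rows.
#' @export
extract_embeddings <- function(model, sequences, T = 48L, batch_size = 256L) {
  stopifnot(inherits(model, "gait_transformer"))
  n <- length(sequences)
  if (n == 0L) stop("no sequences")
  tokens <- array(0, c(n, T, TOKEN_DIM))
  for (i in seq_len(n))
    tokens[i, , ] <- flatten_sequence(center_crop(sequences[[i]], T))
  out <- matrix(0, n, model$config$emb_dim)
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, n)
    out[lo:hi, ] <- gait_forward(model, tokens[lo:hi, , , drop = FALSE])$embedding
  }
  l2_normalize_rows(out)
}

#' Rank-1 gallery/probe accuracy
#'
#' For each probe embedding, finds the nearest gallery embedding by cosine
#' similarity (the dot product of unit vectors) and scores a hit when the
#' top-1 gallery subject matches the probe subject. Ties break toward the
#' first gallery index.
#'
#' @param gallery_emb,probe_emb unit-norm embedding matrices.
#' @param gallery_ids,probe_ids subject labels aligned to the rows.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
rank1_accuracy <- function(gallery_emb, gallery_ids, probe_emb, probe_ids) {
  gallery_emb <- as.matrix(gallery_emb); probe_emb <- as.matrix(probe_emb)
  if (nrow(gallery_emb) == 0L) stop("empty gallery")
  if (nrow(probe_emb) == 0L) stop("empty probe set")
  sims <- tcrossprod(probe_emb, gallery_emb)
  best <- apply(sims, 1L, which.max)          # which.max = first tie wins
  100 * mean(gallery_ids[best] == probe_ids)
}

#' Cross-view rank-1 protocol
#'
#' For every view `v`, the probe set is all items recorded at `v` and the
#' gallery is every item at any other view; rank-1 accuracy is computed per
#' view and averaged. Probes whose subject never appears in their
#' cross-view gallery are skipped (with a warning) and counted in the
#' coverage statistic.
#'
#' @param embeddings unit-norm `N x d` matrix.
#' @param subjects,views per-row subject and view labels (at least two
#'   distinct views).
#' @return List with `per_view` (named accuracy vector), `mean`, and
#'   `coverage` (fraction of probes evaluable).
#' @export
cross_view_rank1 <- function(embeddings, subjects, views) {
  embeddings <- as.matrix(embeddings)
  uv <- unique(views)
  if (length(uv) < 2L) stop("cross-view protocol needs at least 2 views")
  acc <- stats::setNames(numeric(0), character(0))
  n_eval <- 0L; n_total <- 0L
  for (v in uv) {
    probe <- which(views == v)
    gallery <- which(views != v)
    ok <- subjects[probe] %in% subjects[gallery]
    n_total <- n_total + length(probe)
    if (!all(ok)) {
      warning(sprintf("view %s: %d probe(s) without a cross-view gallery subject skipped",
                      v, sum(!ok)))
      probe <- probe[ok]
    }
    if (length(probe) == 0L) next
    n_eval <- n_eval + length(probe)
    acc[as.character(v)] <- rank1_accuracy(
      embeddings[gallery, , drop = FALSE], subjects[gallery],
      embeddings[probe, , drop = FALSE], subjects[probe])
  }
  list(per_view = acc, mean = mean(acc), coverage = n_eval / n_total)
}

#' Gender precision, recall and F1
#'
#' Thresholds probabilities at 0.5 and macro-averages precision, recall
#' and F1 over the two classes (each class in turn treated as positive),
#' so the minority class weighs equally. Both classes must be present in
#' the truth.
#'
#' @param y_true 0/1 vector.
#' @param y_prob predicted probabilities (or 0/1 predictions).
#' @return Named vector `precision`, `recall`, `f1`, as percentages.
#' @export
gender_metrics <- function(y_true, y_prob) {
  y_true <- as.numeric(y_true)
  if (length(unique(y_true)) < 2L)
    stop("both classes must be present in y_true")
  y_hat <- as.numeric(y_prob >= 0.5)
  per_class <- function(cls) {
    tp <- sum(y_hat == cls & y_true == cls)
    fp <- sum(y_hat == cls & y_true != cls)
    fn <- sum(y_hat != cls & y_true == cls)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  }
  m <- (per_class(0) + per_class(1)) / 2
  c(precision = 100 * m[["p"]], recall = 100 * m[["r"]], f1 = 100 * m[["f"]])
}

#' Per-attribute coefficient of determination
#'
#' For each attribute column, `R^2 = 1 - SS_res / SS_tot` with `SS_tot`
#' taken about the target mean — the agreement between the appearance
#' head and the soft pseudo-labels. Attributes whose target has zero
#' variance are reported as `NA` (undefined), never as 0.
#'
#' @param pred,target numeric `N x K` matrices (`N >= 2`).
#' @return Named numeric vector of `K` scores (`<= 1`, possibly `NA`).
#' @export
attribute_r2 <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  stopifnot(nrow(pred) == nrow(target), ncol(pred) == ncol(target),
            nrow(pred) >= 2L)
  out <- numeric(ncol(target))
  for (k in seq_len(ncol(target))) {
    ss_tot <- sum((target[, k] - mean(target[, k]))^2)
    if (ss_tot == 0) { out[k] <- NA_real_; next }
    out[k] <- 1 - sum((pred[, k] - target[, k])^2) / ss_tot
  }
  names(out) <- colnames(target)
  out
}

#' Full evaluation report
#'
#' Convenience wrapper combining the protocols: cross-view rank-1 (when
#' view tags are given), gender metrics (when 0/1 gender labels are given)
#' and per-attribute R^2 (when attribute targets are given).
#'
#' @param model a [gait_transformer()].
#' @param sequences list of [gait_sequence()].
#' @param subjects subject ids per sequence.
#' @param views,genders,attr_targets optional per-sequence metadata.
#' @param T evaluation crop.
#' @return A list of class `gait_eval_report`.
#' @export
evaluate_model <- function(model, sequences, subjects, views = NULL,
                           genders = NULL, attr_targets = NULL, T = 48L) {
  emb <- extract_embeddings(model, sequences, T)
  rep <- list()
  if (!is.null(views))
    rep$cross_view <- cross_view_rank1(emb, subjects, views)
  if (!is.null(genders)) {
    tokens <- NULL
    if (is.null(model$params$head.gender.W))
      stop("model has no gender head; fine-tune with task = 'gender' first")
    probs <- numeric(length(sequences))
    for (i in seq_along(sequences)) {
      fw <- gait_forward(model, flatten_sequence(center_crop(sequences[[i]], T)))
      logit <- fw$embedding %*% model$params$head.gender.W +
        model$params$head.gender.b[1L]
      probs[i] <- 1 / (1 + exp(-logit))
    }
    rep$gender <- gender_metrics(genders, probs)
  }
  if (!is.null(attr_targets)) {
    preds <- matrix(0, length(sequences), ncol(attr_targets))
    for (i in seq_along(sequences))
      preds[i, ] <- gait_forward(
        model, flatten_sequence(center_crop(sequences[[i]], T)))$attributes
    colnames(preds) <- colnames(attr_targets)
    rep$attribute_r2 <- attribute_r2(preds, attr_targets)
  }
  structure(rep, class = "gait_eval_report")
}

#' @export
print.gait_eval_report <- function(x, ...) {
  cat("<gait_eval_report>\n")
  if (!is.null(x$cross_view))
    cat(sprintf("  cross-view rank-1: mean %.2f%% over %d views (coverage %.0f%%)\n",
                x$cross_view$mean, length(x$cross_view$per_view),
                100 * x$cross_view$coverage))
  if (!is.null(x$gender))
    cat(sprintf("  gender (macro): P %.2f%% R %.2f%% F1 %.2f%%\n",
                x$gender["precision"], x$gender["recall"], x$gender["f1"]))
  if (!is.null(x$attribute_r2))
    cat(sprintf("  attribute R^2: mean %.3f over %d defined attributes\n",
                mean(x$attribute_r2, na.rm = TRUE), sum(!is.na(x$attribute_r2))))
  invisible(x)
}
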