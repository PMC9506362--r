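#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: %d layers, d_model %d, %d heads, ff %d, max_len %d>\n",
              x$n_layers, x$d_model, x$n_heads, x$ff_dim, x$max_len))
  invisible(x)
}

#' @export
print.training_config <- function(x, ...) {
  cat(sprintf(paste0("<training_config: tau %g, lambda %g, batch %d views, ",
                     "%d epochs, lr %g..%g /%d>\n"),
              x$tau, x$lambda_app, x$batch_size, x$epochs,
              x$lr_lo, x$lr_hi, x$lr_cycle_epochs))
  invisible(x)
}

#' @export
print.gait_transformer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Pose-token transformer (%d layers, d_model %d, %s parameters)\n",
              cfg$n_layers, cfg$d_model,
              format(count_parameters(x), big.mark = ",")))
  if (is.null(x$history)) {
    cat("  untrained (freshly initialized)\n")
  } else {
    cat(sprintf("  trained: %s, %d epochs, final loss %.4f\n",
                x$mode %||% x$task %||% "?", nrow(x$history),
                x$history$loss[nrow(x$history)]))
  }
  invisible(x)
}

#' Summarize a gait transformer
#'
#' @param object a [gait_transformer()].
#' @param ... unused.
#' @export
summary.gait_transformer <- function(object, ...) {
  print(object)
  cat("\nConfig:\n")
  cfg <- object$config
  for (nm in names(cfg)) cat(sprintf("  %-12s %s\n", nm, cfg[[nm]]))
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' Model coefficients
#'
#' Returns the named list of parameter tensors.
#'
#' @param object a [gait_transformer()].
#' @param ... unused.
#' @export
coef.gait_transformer <- function(object, ...) object$params

#' Predict from a gait transformer
#'
#' Runs the deterministic evaluation path on new sequences and returns the
#' requested output: l2-normalized identity `"embedding"`s, the raw
#' contrastive `"projection"`, sigmoid `"attributes"`, or `"gender"`
#' probabilities (requires a gender-fine-tuned model).
#'
#' @param object a [gait_transformer()].
#' @param newdata a `gait_dataset`, a list of [gait_sequence()], a single
#'   [gait_sequence()], or a `B x T x 54` token array.
#' @param type output type.
#' @param T evaluation crop length.
#' @param ... unused.
#' @return A numeric matrix with one row per sequence.
#' @export
predict.gait_transformer <- function(object, newdata,
                                     type = c("embedding", "projection",
                                              "attributes", "gender"),
                                     T = 48L, ...) {
  type <- match.arg(type)
  sequences <- NULL
  if (inherits(newdata, "gait_dataset")) sequences <- newdata$sequences
  else if (inherits(newdata, "gait_sequence")) sequences <- list(newdata)
  else if (is.list(newdata)) sequences <- newdata
  if (!is.null(sequences)) {
    tokens <- array(0, c(length(sequences), T, TOKEN_DIM))
    for (i in seq_along(sequences))
      tokens[i, , ] <- flatten_sequence(center_crop(sequences[[i]], T))
  } else {
    tokens <- newdata
    if (is.matrix(tokens)) tokens <- array(tokens, c(1L, dim(tokens)))
  }
  fw <- gait_forward(object, tokens)
  switch(type,
    embedding = l2_normalize_rows(fw$embedding),
    projection = fw$projection,
    attributes = {
      a <- fw$attributes
      if (!is.null(object$attr_names)) colnames(a) <- object$attr_names
      a
    },
    gender = {
      if (is.null(object$params$head.gender.W))
        stop("model has no gender head; run gait_finetune(task = 'gender')")
      logit <- fw$embedding %*% object$params$head.gender.W +
        object$params$head.gender.b[1L]
      1 / (1 + exp(-logit))
    })
}

#' Plot the training history
#'
#' Loss (and its contrastive/appearance components when present) against
#' epoch, with the learning-rate schedule in a lower panel.
#'
#' @param x a trained [gait_transformer()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.gait_transformer <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss", ...)
  if (!all(is.na(h$loss_supcon %||% NA)))
    graphics::lines(h$epoch, h$loss_supcon, lty = 2)
  graphics::plot(h$epoch, h$lr, type = "l", xlab = "epoch", ylab = "learning rate")
  invisible(x)
}
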