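#' Transformer model configuration
#'
#' Architecture hyper-parameters of the pose-token transformer encoder.
#' Flattened 54-d skeleton tokens are linearly projected to `d_model`, a
#' learnable positional embedding is added (not concatenated), `n_layers`
#' standard post-norm encoder layers are applied, token representations are
#' mean-pooled over time, and three linear heads hang off the pooled
#' representation: a `emb_dim` identity embedding, a `proj_dim` contrastive
#' projection (the vector the contrastive loss sees) and an `n_attributes`
#' appearance head with sigmoid outputs.
#'
#' The stock sizes are `"sm"` (4 layers), `"md"` (8) and `"xl"` (12), all
#' with `d_model = 256`, 8 attention heads and feed-forward width 512.
#'
#' @param n_layers number of encoder layers.
#' @param d_model token/channel width; must be divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param ff_dim feed-forward hidden width.
#' @param max_len positional table length (maximum sequence length).
#' @param emb_dim identity embedding width.
#' @param proj_dim contrastive projection width.
#' @param n_attributes appearance head width.
#' @return A list of class `model_config`.
#' @export
#' @examples
#' model_config("sm")$n_layers
model_config <- function(n_layers = 4L, d_model = 256L, n_heads = 8L,
                         ff_dim = 512L, max_len = 48L, emb_dim = 256L,
                         proj_dim = 128L, n_attributes = 42L) {
  if (is.character(n_layers)) {
    n_layers <- switch(match.arg(n_layers, c("sm", "md", "xl")),
                       sm = 4L, md = 8L, xl = 12L)
  }
  stopifnot(d_model %% n_heads == 0, n_layers >= 1, max_len >= 1)
  structure(list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
                 max_len = as.integer(max_len), emb_dim = as.integer(emb_dim),
                 proj_dim = as.integer(proj_dim),
                 n_attributes = as.integer(n_attributes)),
            class = "model_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build a pose-token transformer
#'
#' Instantiates the full component inventory of [model_config()]: input
#' projection `54 -> d_model` (with bias), learnable additive positional
#' table `max_len x d_model`, `n_layers` post-norm encoder layers
#' (self-attention with q/k/v/out projections and biases, a two-layer
#' feed-forward `d_model -> ff_dim -> d_model` with biases and ReLU, two
#' per-layer normalizations with learnable scale and shift), temporal mean
#' pooling, and the embedding / contrastive / appearance heads.
#' Initialization is Glorot-uniform weights, zero biases, unit layer-norm
#' scales and a small-normal positional table; seed the R RNG beforehand
#' for reproducible builds.
#'
#' @param config a [model_config()].
#' @return An object of class `gait_transformer`: list with `config`,
#'   `params` (named list of numeric arrays) and `history` (`NULL` until
#'   trained).
#' @seealso [gait_pretrain()], [gait_forward()], [count_parameters()]
#' @export
gait_transformer <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d_model; ff <- config$ff_dim
  p <- list(
    proj.W = glorot(TOKEN_DIM, d), proj.b = numeric(d),
    pos = matrix(stats::rnorm(config$max_len * d, 0, 0.02), config$max_len, d)
  )
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("enc%d.", l)
    p[[paste0(pre, "Wq")]] <- glorot(d, d); p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "Wk")]] <- glorot(d, d); p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "Wv")]] <- glorot(d, d); p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "Wo")]] <- glorot(d, d); p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "ln1.g")]] <- rep(1, d); p[[paste0(pre, "ln1.b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- glorot(d, ff); p[[paste0(pre, "b1")]] <- numeric(ff)
    p[[paste0(pre, "W2")]] <- glorot(ff, d); p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "ln2.g")]] <- rep(1, d); p[[paste0(pre, "ln2.b")]] <- numeric(d)
  }
  p$emb.W <- glorot(d, config$emb_dim); p$emb.b <- numeric(config$emb_dim)
  p$head.proj.W <- glorot(config$emb_dim, config$proj_dim)
  p$head.proj.b <- numeric(config$proj_dim)
  p$head.attr.W <- glorot(config$emb_dim, config$n_attributes)
  p$head.attr.b <- numeric(config$n_attributes)
  structure(list(config = config, params = p, history = NULL),
            class = "gait_transformer")
}

#' Count trainable parameters
#'
#' Total number of trainable scalars in the model. For the stock sizes this
#' reproduces the printed totals: sm 2,244,266 (2.24M), md 4,352,682
#' (4.35M), xl 6,461,098 (6.46M).
#'
#' @param model a [gait_transformer()].
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "gait_transformer"))
  sum(vapply(model$params, length, integer(1)))
}

layer_norm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * invstd
  y <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(y = y, xhat = xhat, invstd = invstd)
}

layer_norm_bwd <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$invstd * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx,
       dg = colSums(dy * cache$xhat),
       db = colSums(dy))
}

#' Run the transformer forward
#'
#' Forward pass on a batch of token sequences. Deterministic for fixed
#' weights and input (there is no dropout). The positional embedding rows
#' `1..T` are added to the projected tokens; `T` may be any length up to
#' `max_len` — temporal mean pooling makes the output shapes independent
#' of `T`.
#'
#' @param model a [gait_transformer()].
#' @param tokens numeric `B x T x 54` array (or `T x 54` matrix for a
#'   single sequence) of flattened skeletons.
#' @param cache keep intermediate activations for backpropagation
#'   (internal use).
#' @return List with `embedding` (`B x emb_dim`), `projection`
#'   (`B x proj_dim`, pre-normalization), `attributes` (`B x n_attributes`,
#'   sigmoid probabilities) and, if requested, `cache`.
#' @export
gait_forward <- function(model, tokens, cache = FALSE) {
  stopifnot(inherits(model, "gait_transformer"))
  if (is.matrix(tokens)) tokens <- array(tokens, c(1L, dim(tokens)))
  B <- dim(tokens)[1L]; T <- dim(tokens)[2L]
  cfg <- model$config; p <- model$params
  if (T > cfg$max_len)
    stop(sprintf("sequence length %d exceeds max_len %d", T, cfg$max_len))
  if (dim(tokens)[3L] != TOKEN_DIM) stop("tokens must have 54 channels")
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  # rows grouped per sequence, frame index fastest: row (b-1)*T + t
  M <- matrix(aperm(tokens, c(2L, 1L, 3L)), nrow = B * T, ncol = TOKEN_DIM)
  H <- sweep(M %*% p$proj.W, 2L, p$proj.b, `+`)
  H <- H + p$pos[rep(seq_len(T), times = B), , drop = FALSE]
  cc <- if (cache) list(M = M, B = B, T = T, layers = vector("list", cfg$n_layers))
  blocks <- split(seq_len(B * T), rep(seq_len(B), each = T))
  hcols <- lapply(seq_len(nh), function(h) ((h - 1L) * dh + 1L):(h * dh))
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc%d.", l)
    Hin <- H
    Q <- sweep(Hin %*% p[[paste0(pre, "Wq")]], 2L, p[[paste0(pre, "bq")]], `+`)
    K <- sweep(Hin %*% p[[paste0(pre, "Wk")]], 2L, p[[paste0(pre, "bk")]], `+`)
    V <- sweep(Hin %*% p[[paste0(pre, "Wv")]], 2L, p[[paste0(pre, "bv")]], `+`)
    O <- matrix(0, B * T, d)
    AW <- if (cache) array(0, c(T, T, nh, B))
    scale <- 1 / sqrt(dh)
    for (b in seq_len(B)) {
      rows <- blocks[[b]]
      for (h in seq_len(nh)) {
        cols <- hcols[[h]]
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) * scale
        S <- S - apply(S, 1L, max)
        E <- exp(S)
        A <- E / rowSums(E)
        O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
        if (cache) AW[, , h, b] <- A
      }
    }
    attn_out <- sweep(O %*% p[[paste0(pre, "Wo")]], 2L, p[[paste0(pre, "bo")]], `+`)
    R1 <- Hin + attn_out
    ln1 <- layer_norm_fwd(R1, p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
    H1 <- ln1$y
    Z1 <- sweep(H1 %*% p[[paste0(pre, "W1")]], 2L, p[[paste0(pre, "b1")]], `+`)
    Arelu <- pmax(Z1, 0)
    FF <- sweep(Arelu %*% p[[paste0(pre, "W2")]], 2L, p[[paste0(pre, "b2")]], `+`)
    R2 <- H1 + FF
    ln2 <- layer_norm_fwd(R2, p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
    if (cache)
      cc$layers[[l]] <- list(Hin = Hin, Q = Q, K = K, V = V, O = O, AW = AW,
                             ln1 = ln1, H1 = H1, Z1 = Z1, Arelu = Arelu,
                             ln2 = ln2)
    H <- ln2$y
  }
  pooled <- rowsum(H, group = rep(seq_len(B), each = T), reorder = FALSE) / T
  dimnames(pooled) <- NULL
  emb <- sweep(pooled %*% p$emb.W, 2L, p$emb.b, `+`)
  proj <- sweep(emb %*% p$head.proj.W, 2L, p$head.proj.b, `+`)
  attr_logits <- sweep(emb %*% p$head.attr.W, 2L, p$head.attr.b, `+`)
  attrs <- 1 / (1 + exp(-attr_logits))
  out <- list(embedding = emb, projection = proj, attributes = attrs)
  if (cache) {
    cc$H_final <- H; cc$pooled <- pooled; cc$emb <- emb
    cc$attr_logits <- attr_logits
    out$cache <- cc
  }
  out
}

# Backward pass. d_out: list with any of d_emb (B x emb, gradient flowing
# straight into the embedding), d_proj (B x proj) and d_attr_logits
# (B x n_attr, gradient at the sigmoid's input). Returns named gradients
# matching model$params.
gait_backward <- function(model, cache, d_out) {
  cfg <- model$config; p <- model$params
  B <- cache$B; T <- cache$T
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  g <- list()
  d_emb <- matrix(0, B, cfg$emb_dim)
  if (!is.null(d_out$d_emb)) d_emb <- d_emb + d_out$d_emb
  if (!is.null(d_out$d_proj)) {
    g$head.proj.W <- crossprod(cache$emb, d_out$d_proj)
    g$head.proj.b <- colSums(d_out$d_proj)
    d_emb <- d_emb + tcrossprod(d_out$d_proj, p$head.proj.W)
  } else {
    g$head.proj.W <- matrix(0, cfg$emb_dim, cfg$proj_dim)
    g$head.proj.b <- numeric(cfg$proj_dim)
  }
  if (!is.null(d_out$d_attr_logits)) {
    g$head.attr.W <- crossprod(cache$emb, d_out$d_attr_logits)
    g$head.attr.b <- colSums(d_out$d_attr_logits)
    d_emb <- d_emb + tcrossprod(d_out$d_attr_logits, p$head.attr.W)
  } else {
    g$head.attr.W <- matrix(0, cfg$emb_dim, cfg$n_attributes)
    g$head.attr.b <- numeric(cfg$n_attributes)
  }
  g$emb.W <- crossprod(cache$pooled, d_emb)
  g$emb.b <- colSums(d_emb)
  d_pooled <- tcrossprod(d_emb, p$emb.W)
  dH <- d_pooled[rep(seq_len(B), each = T), , drop = FALSE] / T
  blocks <- split(seq_len(B * T), rep(seq_len(B), each = T))
  hcols <- lapply(seq_len(nh), function(h) ((h - 1L) * dh + 1L):(h * dh))
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("enc%d.", l); lc <- cache$layers[[l]]
    ln2b <- layer_norm_bwd(dH, lc$ln2, p[[paste0(pre, "ln2.g")]])
    g[[paste0(pre, "ln2.g")]] <- ln2b$dg
    g[[paste0(pre, "ln2.b")]] <- ln2b$db
    dR2 <- ln2b$dx
    # feed-forward branch
    dFF <- dR2
    g[[paste0(pre, "W2")]] <- crossprod(lc$Arelu, dFF)
    g[[paste0(pre, "b2")]] <- colSums(dFF)
    dZ1 <- tcrossprod(dFF, p[[paste0(pre, "W2")]]) * (lc$Z1 > 0)
    g[[paste0(pre, "W1")]] <- crossprod(lc$H1, dZ1)
    g[[paste0(pre, "b1")]] <- colSums(dZ1)
    dH1 <- dR2 + tcrossprod(dZ1, p[[paste0(pre, "W1")]])
    ln1b <- layer_norm_bwd(dH1, lc$ln1, p[[paste0(pre, "ln1.g")]])
    g[[paste0(pre, "ln1.g")]] <- ln1b$dg
    g[[paste0(pre, "ln1.b")]] <- ln1b$db
    dR1 <- ln1b$dx
    d_attnout <- dR1
    g[[paste0(pre, "Wo")]] <- crossprod(lc$O, d_attnout)
    g[[paste0(pre, "bo")]] <- colSums(d_attnout)
    dO <- tcrossprod(d_attnout, p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, B * T, d); dK <- matrix(0, B * T, d); dV <- matrix(0, B * T, d)
    scale <- 1 / sqrt(dh)
    for (b in seq_len(B)) {
      rows <- blocks[[b]]
      for (h in seq_len(nh)) {
        cols <- hcols[[h]]
        A <- lc$AW[, , h, b]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- lc$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A)) * scale
        dQ[rows, cols] <- dS %*% lc$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- crossprod(dS, lc$Q[rows, cols, drop = FALSE])
      }
    }
    g[[paste0(pre, "Wq")]] <- crossprod(lc$Hin, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(lc$Hin, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(lc$Hin, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dH <- dR1 +
      tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, p[[paste0(pre, "Wv")]])
  }
  g$pos <- rowsum(dH, group = rep(seq_len(T), times = B), reorder = TRUE)
  if (nrow(g$pos) < cfg$max_len)
    g$pos <- rbind(g$pos, matrix(0, cfg$max_len - nrow(g$pos), d))
  g$proj.W <- crossprod(cache$M, dH)
  g$proj.b <- colSums(dH)
  g[names(model$params)]
}
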