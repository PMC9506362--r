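# Independent brute-force oracles used to check the vectorized paths.

# naive double-loop supervised contrastive loss (mean over anchors)
supcon_naive <- function(Z, labels, tau) {
  Z <- as.matrix(Z)
  Z <- Z / pmax(sqrt(rowSums(Z^2)), 1e-12)
  n <- nrow(Z)
  total <- 0
  for (i in seq_len(n)) {
    A <- setdiff(seq_len(n), i)
    P <- A[labels[A] == labels[i]]
    stopifnot(length(P) > 0)
    li <- 0
    logits <- sapply(A, function(a) sum(Z[i, ] * Z[a, ]) / tau)
    mx <- max(logits)
    lse <- mx + log(sum(exp(logits - mx)))
    for (p in P) {
      li <- li - (sum(Z[i, ] * Z[p, ]) / tau - lse)
    }
    total <- total + li / length(P)
  }
  total / n
}

# naive rank-1: loop over probes, explicit cosine comparisons
rank1_naive <- function(gal_emb, gal_ids, probe_emb, probe_ids) {
  hits <- 0
  for (i in seq_len(nrow(probe_emb))) {
    sims <- apply(gal_emb, 1L, function(g) sum(g * probe_emb[i, ]))
    hits <- hits + (gal_ids[which.max(sims)] == probe_ids[i])
  }
  100 * hits / nrow(probe_emb)
}

# a plausible random skeleton frame: upright body, distinct shoulders/hips
random_frame <- function() {
  lay <- joint_layout()
  f <- matrix(stats::rnorm(18 * 3, sd = 5), 18, 3)
  f[, 3] <- stats::runif(18)
  cx <- stats::runif(1, 100, 500); cy <- stats::runif(1, 100, 400)
  w <- stats::runif(1, 20, 60); h <- stats::runif(1, 50, 120)
  f[lay$l_hip, 1:2] <- c(cx - w / 3, cy)
  f[lay$r_hip, 1:2] <- c(cx + w / 3, cy)
  f[lay$l_shoulder, 1:2] <- c(cx - w / 2, cy - h)
  f[lay$r_shoulder, 1:2] <- c(cx + w / 2, cy - h)
  f[lay$neck, 1:2] <- c(cx, cy - h)
  f
}

# constant-confidence tracklet with controllable per-frame coordinates
const_tracklet <- function(n = 10, fps = 24, conf = 0.9, drift = 0) {
  dat <- array(0, c(n, 18, 3))
  base <- random_frame()
  for (t in seq_len(n)) {
    dat[t, , 1:2] <- base[, 1:2] + (t - 1) * drift
    dat[t, , 3] <- conf
  }
  gait_tracklet(dat, fps = fps)
}

tiny_model_config <- function() {
  model_config(n_layers = 2L, d_model = 16L, n_heads = 2L, ff_dim = 24L,
               max_len = 12L, emb_dim = 16L, proj_dim = 8L, n_attributes = 5L)
}
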