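test_that("supcon loss reproduces closed-form worked examples", {
  # a single positive pair is a one-term ratio of identical exponentials
  expect_equal(supcon_loss(rbind(c(1, 0), c(0.2, 0.9)), c("a", "a"),
                           tau = 0.001), 0)
  # 4 unit samples, 2 classes, tau = 1: every anchor contributes
  # -log(e / (e + 2)), so the mean is log(e + 2) - 1
  Z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(supcon_loss(Z, c(1, 1, 2, 2), tau = 1), log(exp(1) + 2) - 1)
  # violations of the sampler contract are errors
  expect_error(supcon_loss(Z, c(1, 2, 3, 4), tau = 1), "positive")
  expect_error(supcon_loss(Z[1, , drop = FALSE], 1, tau = 1), "2 samples")
})

test_that("vectorized supcon equals the naive double-loop oracle", {
  set.seed(55)
  for (i in 1:25) {
    N <- sample(2:8, 1)
    labels <- rep(seq_len(N), 2)         # two views per tracklet
    Z <- matrix(rnorm(2 * N * 6), 2 * N, 6)
    tau <- sample(c(1, 0.01, 0.001), 1)
    expect_equal(supcon_loss(Z, labels, tau), supcon_naive(Z, labels, tau),
                 tolerance = 1e-6)
  }
})

test_that("supcon is invariant to sample permutation and common rotation", {
  set.seed(66)
  N <- 6
  Z <- matrix(rnorm(2 * N * 8), 2 * N, 8)
  labels <- rep(seq_len(N), 2)
  base <- supcon_loss(Z, labels, tau = 0.01)
  perm <- sample(2 * N)
  expect_equal(supcon_loss(Z[perm, ], labels[perm], tau = 0.01), base)
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))   # random orthogonal matrix
  expect_equal(supcon_loss(Z %*% Q, labels, tau = 0.01), base)
})

test_that("supcon analytic gradient matches finite differences", {
  set.seed(77)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  labels <- rep(1:3, 2)
  sc <- supcon_loss(Z, labels, tau = 0.05, grad = TRUE)
  eps <- 1e-6
  for (i in sample(length(Z), 8)) {
    Zp <- Z; Zp[i] <- Zp[i] + eps
    Zm <- Z; Zm[i] <- Zm[i] - eps
    num <- (supcon_loss(Zp, labels, 0.05) - supcon_loss(Zm, labels, 0.05)) /
      (2 * eps)
    expect_equal(sc$grad[i], num, tolerance = 1e-5)
  }
})

test_that("soft BCE reproduces worked values and is minimized at p = y", {
  expect_equal(soft_bce(0.5, 0.5), log(2))
  expect_lt(soft_bce(1 - 1e-9, 1), 1e-6)
  expect_equal(soft_bce(0.6, 0.7), -(0.7 * log(0.6) + 0.3 * log(0.4)),
               tolerance = 1e-12)
  for (y in c(0.2, 0.5, 0.8)) {
    grid <- seq(0.01, 0.99, by = 0.01)
    vals <- vapply(grid, function(p) soft_bce(p, y), numeric(1))
    expect_equal(grid[which.min(vals)], y)
  }
  # extreme predictions are clamped, not infinite
  expect_true(is.finite(soft_bce(0, 1)))
})

test_that("combined loss is linear in the appearance term", {
  expect_equal(combined_loss(1.0, 0.5, 0.5), 1.25)
  expect_equal(combined_loss(0.8, 123, 0), 0.8)
  expect_equal(combined_loss(0.7, 0, 0.5), 0.7)
  l0 <- combined_loss(1, 0, 0.5); l1 <- combined_loss(1, 1, 0.5)
  l2 <- combined_loss(1, 2, 0.5)
  expect_equal(l1 - l0, 0.5)
  expect_equal(l2 - l1, 0.5)
})

test_that("learning-rate schedules hit their anchor points", {
  cfg <- training_config()
  expect_equal(cyclical_lr(0, cfg), 1e-4)
  expect_equal(cyclical_lr(10, cfg), 1e-3)
  expect_equal(cyclical_lr(20, cfg), 1e-4)
  expect_equal(cyclical_lr(5, cfg), (1e-4 + 1e-3) / 2)
  expect_equal(cyclical_lr(30, cfg), 1e-3)       # periodicity
  expect_equal(linear_lr(0), 1e-4)
  expect_equal(linear_lr(100), 5e-5)
  expect_equal(linear_lr(200), 0)
  expect_equal(linear_lr(300), 0)                # floored at zero
})

test_that("LLRD groups decay geometrically from heads to input", {
  set.seed(1)
  m <- gait_transformer(model_config(n_layers = 4, d_model = 16, n_heads = 2,
                                     ff_dim = 16, emb_dim = 16, proj_dim = 8,
                                     n_attributes = 3))
  r <- llrd_param_groups(m, lr0 = 1e-4, decay = 0.9)
  expect_equal(unname(r["head.proj.W"]), 1e-4)
  expect_equal(unname(r["emb.W"]), 1e-4)
  expect_equal(unname(r["enc4.Wq"]), 1e-4 * 0.9)        # top layer
  expect_equal(unname(r["enc1.Wq"]), 1e-4 * 0.9^4)      # bottom layer
  expect_equal(unname(r["proj.W"]), 1e-4 * 0.9^5)
  expect_equal(unname(r["pos"]), 1e-4 * 0.9^5)
  # non-increasing from heads down to the input projection
  ordered <- c(r["head.attr.W"], r["enc4.W1"], r["enc3.W1"], r["enc2.W1"],
               r["enc1.W1"], r["proj.W"])
  expect_true(all(diff(unname(ordered)) <= 0))
  r1 <- llrd_param_groups(m, lr0 = 2e-4, decay = 1)
  expect_true(all(r1 == 2e-4))
})

make_smoke_dataset <- function(n_ids, seed) {
  corpus_dataset(make_pretraining_corpus(n_ids, frames_per_id = 100L,
                                         seed = seed))
}

test_that("contrastive pretraining decreases the loss and is replayable", {
  ds <- make_smoke_dataset(10, seed = 5)
  mcfg <- model_config(n_layers = 1, d_model = 16, n_heads = 2, ff_dim = 24,
                       emb_dim = 16, proj_dim = 8)
  tcfg <- training_config(epochs = 15, batch_size = 20, seed = 5)
  m1 <- gait_pretrain(ds, mcfg, tcfg, mode = "contrastive")
  expect_lt(mean(tail(m1$history$loss_supcon, 3)),
            mean(head(m1$history$loss_supcon, 3)))
  m2 <- gait_pretrain(ds, mcfg, tcfg, mode = "contrastive")
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("contrastive mode leaves the appearance head untouched", {
  ds <- make_smoke_dataset(6, seed = 6)
  set.seed(123)
  m0 <- gait_transformer(model_config(n_layers = 1, d_model = 16, n_heads = 2,
                                      ff_dim = 24, emb_dim = 16, proj_dim = 8))
  w_before <- m0$params$head.attr.W
  m1 <- gait_pretrain(ds, m0, training_config(epochs = 5, batch_size = 12,
                                              seed = 6),
                      mode = "contrastive")
  expect_identical(m1$params$head.attr.W, w_before)
  expect_false(identical(m1$params$proj.W, m0$params$proj.W))
  # multitask without attributes is an error
  ds$attributes <- NULL
  expect_error(gait_pretrain(ds, m0, training_config(epochs = 1, seed = 1),
                             mode = "multitask"), "attributes")
})

test_that("gender fine-tuning separates distinct walkers on the train set", {
  set.seed(9)
  seqs <- list(); labels <- numeric(0)
  for (i in 1:6) {
    w <- sample_walker(i * 13)
    # plant a cleanly separable morphological difference between classes
    labels[i] <- as.numeric(i %% 2 == 0)
    w$params$hip_ratio <- if (labels[i] == 1) 0.92 else 0.58
    seqs[[i]] <- normalize_sequence(render_tracklet(w$params, 100, 24, seed = i))
  }
  set.seed(30)
  m0 <- gait_transformer(model_config(n_layers = 1, d_model = 16, n_heads = 2,
                                      ff_dim = 24, emb_dim = 16, proj_dim = 8))
  tcfg <- training_config(finetune_epochs = 100, finetune_lr0 = 2e-3, seed = 30)
  m <- gait_finetune(m0, seqs, labels, task = "gender", training = tcfg)
  probs <- predict(m, seqs, type = "gender")
  expect_equal(as.numeric(probs >= 0.5), labels)
  # frozen-seed replay reproduces the final weights
  m2 <- gait_finetune(m0, seqs, labels, task = "gender", training = tcfg)
  expect_identical(m$params, m2$params)
  expect_error(gait_finetune(m0, seqs, labels, task = "nonsense"))
})
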