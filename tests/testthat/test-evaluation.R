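random_unit <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

test_that("extracted embeddings are unit-norm, crop-deterministic", {
  set.seed(3)
  m <- gait_transformer(model_config(n_layers = 1, d_model = 16, n_heads = 2,
                                     ff_dim = 24, emb_dim = 16, proj_dim = 8))
  seqs <- lapply(1:3, function(i)
    normalize_sequence(render_tracklet(sample_walker(i)$params, 100, 24,
                                       seed = i)))
  emb <- extract_embeddings(m, seqs)
  expect_equal(sqrt(rowSums(emb^2)), rep(1, 3), tolerance = 1e-6)
  # duplicates give identical embeddings
  emb2 <- extract_embeddings(m, c(seqs, seqs[1]))
  expect_equal(emb2[4, ], emb2[1, ])
  # frames outside the center crop are irrelevant
  s <- seqs[[1]]
  mutated <- s
  mutated$data[1:10, , 1:2] <- 99
  expect_equal(extract_embeddings(m, list(s))[1, ],
               extract_embeddings(m, list(mutated))[1, ])
  expect_error(extract_embeddings(m, list(center_crop(s, 48)), T = 60),
               "shorter")
})

test_that("rank-1 matches worked examples and the brute-force oracle", {
  g <- rbind(c(1, 0), c(0, 1))
  gid <- c("A", "B")
  p <- matrix(c(0.9, 0.1) / sqrt(0.82), 1)
  expect_equal(rank1_accuracy(g, gid, p, "A"), 100)
  expect_equal(rank1_accuracy(g, gid, g, gid), 100)   # probe = gallery
  expect_error(rank1_accuracy(g[0, , drop = FALSE], character(0), p, "A"),
               "gallery")
  set.seed(44)
  for (i in 1:10) {
    G <- random_unit(20, 5); P <- random_unit(15, 5)
    gids <- sample(letters[1:6], 20, replace = TRUE)
    pids <- sample(letters[1:6], 15, replace = TRUE)
    expect_equal(rank1_accuracy(G, gids, P, pids),
                 rank1_naive(G, gids, P, pids))
  }
})

test_that("random embeddings score at chance level", {
  set.seed(45)
  G <- 5
  accs <- replicate(60, {
    gal <- random_unit(G, 16)
    probe <- random_unit(40, 16)
    rank1_accuracy(gal, seq_len(G), probe, sample(seq_len(G), 40, TRUE))
  })
  expect_equal(mean(accs), 100 / G, tolerance = 0.15)
})

test_that("rank-1 is invariant to a common orthogonal rotation", {
  set.seed(46)
  G <- random_unit(30, 8); P <- random_unit(20, 8)
  gids <- sample(1:8, 30, TRUE); pids <- sample(1:8, 20, TRUE)
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  expect_equal(rank1_accuracy(G %*% Q, gids, P %*% Q, pids),
               rank1_accuracy(G, gids, P, pids))
})

test_that("cross-view protocol matches per-view brute force", {
  set.seed(47)
  n <- 40
  emb <- random_unit(n, 6)
  subjects <- sample(letters[1:5], n, TRUE)
  views <- sample(c("v0", "v45", "v90", "v135"), n, TRUE)
  res <- cross_view_rank1(emb, subjects, views)
  for (v in unique(views)) {
    probe <- which(views == v); gallery <- which(views != v)
    probe <- probe[subjects[probe] %in% subjects[gallery]]
    expect_equal(unname(res$per_view[v]),
                 rank1_naive(emb[gallery, , drop = FALSE], subjects[gallery],
                             emb[probe, , drop = FALSE], subjects[probe]))
  }
  expect_equal(res$mean, mean(res$per_view))
  # view-invariant embeddings give perfect cross-view recognition
  subj2 <- rep(1:4, each = 2)
  emb2 <- random_unit(4, 6)[subj2, ]
  views2 <- rep(c("a", "b"), 4)
  res2 <- cross_view_rank1(emb2, subj2, views2)
  expect_equal(unname(res2$per_view), c(100, 100))
  expect_error(cross_view_rank1(emb2, subj2, rep("a", 8)), "2 views")
  # probes without cross-view gallery coverage are skipped with a warning
  expect_warning(
    res3 <- cross_view_rank1(rbind(emb2, random_unit(1, 6)),
                             c(subj2, 99), c(views2, "a")),
    "skipped")
  expect_lt(res3$coverage, 1)
})

test_that("gender metrics macro-average the two classes", {
  perfect <- gender_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(unname(perfect), c(100, 100, 100))
  # truth (1,1,0,0), preds (1,0,0,0): macro-F1 = (66.7 + 80) / 2
  m <- gender_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(unname(m["precision"]), 100 * (1 + 2 / 3) / 2, tolerance = 1e-10)
  expect_equal(unname(m["recall"]), 100 * (0.5 + 1) / 2, tolerance = 1e-10)
  expect_equal(unname(m["f1"]), 100 * (2 / 3 + 0.8) / 2, tolerance = 1e-10)
  # all-positive predictor on balanced truth: macro recall 50
  ap <- gender_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(unname(ap["recall"]), 50)
  expect_error(gender_metrics(c(1, 1, 1), c(1, 0, 1)), "both classes")
})

test_that("attribute R2 matches closed forms and flags zero variance", {
  t1 <- matrix(c(0, 1), 2, 1)
  expect_equal(unname(attribute_r2(t1, t1)), 1)
  expect_equal(unname(attribute_r2(matrix(0.5, 2, 1), t1)), 0)
  # two-point worked example: 1 - 0.125/0.5
  expect_equal(unname(attribute_r2(matrix(c(0.25, 0.75), 2, 1), t1)), 0.75)
  # zero-variance target is NA, not 0
  expect_true(is.na(attribute_r2(t1, matrix(0.3, 2, 1))))
  # invariant to attribute ordering
  set.seed(48)
  pred <- matrix(runif(30), 10, 3); targ <- matrix(runif(30), 10, 3)
  r <- attribute_r2(pred, targ)
  perm <- c(3, 1, 2)
  expect_equal(unname(attribute_r2(pred[, perm], targ[, perm])),
               unname(r[perm]))
})
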