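test_that("forward produces the contracted output shapes", {
  set.seed(1)
  m <- gait_transformer(tiny_model_config())
  tok <- array(rnorm(3 * 10 * 54), c(3, 10, 54))
  out <- gait_forward(m, tok)
  expect_equal(dim(out$embedding), c(3, 16))
  expect_equal(dim(out$projection), c(3, 8))
  expect_equal(dim(out$attributes), c(3, 5))
  expect_true(all(out$attributes > 0 & out$attributes < 1))
  # output shapes are invariant to T (mean pooling)
  out2 <- gait_forward(m, tok[, 1:4, , drop = FALSE])
  expect_equal(dim(out2$embedding), c(3, 16))
  expect_error(gait_forward(m, array(0, c(1, 13, 54))), "max_len")
})

test_that("eval-mode forward is deterministic and row-wise independent", {
  set.seed(2)
  m <- gait_transformer(tiny_model_config())
  tok <- array(rnorm(4 * 8 * 54), c(4, 8, 54))
  a <- gait_forward(m, tok); b <- gait_forward(m, tok)
  expect_identical(a$embedding, b$embedding)
  # duplicated sequences give identical rows
  tok[2, , ] <- tok[1, , ]
  out <- gait_forward(m, tok)
  expect_equal(out$embedding[1, ], out$embedding[2, ])
  # permuting the batch permutes the outputs identically
  perm <- c(3, 1, 4, 2)
  outp <- gait_forward(m, tok[perm, , , drop = FALSE])
  expect_equal(outp$embedding, out$embedding[perm, ])
  expect_equal(outp$attributes, out$attributes[perm, ])
})

test_that("two builds from the same seed have identical weights", {
  set.seed(7); m1 <- gait_transformer(tiny_model_config())
  set.seed(7); m2 <- gait_transformer(tiny_model_config())
  expect_identical(m1$params, m2$params)
  set.seed(8); m3 <- gait_transformer(tiny_model_config())
  expect_false(identical(m1$params, m3$params))
})

test_that("parameter totals match the closed-form component sum", {
  per_layer <- function(d, ff) {
    4 * (d * d + d) +                    # q/k/v/out projections with bias
      (d * ff + ff) + (ff * d + d) +     # two-layer feed-forward
      2 * 2 * d                          # two layer norms, scale + shift
  }
  fixed <- function(d, max_len, emb, proj, nattr) {
    (54 * d + d) + max_len * d +
      (d * emb + emb) + (emb * proj + proj) + (emb * nattr + nattr)
  }
  for (cfg in list(tiny_model_config(),
                   model_config("sm"),
                   model_config(n_layers = 3, d_model = 32, n_heads = 4,
                                ff_dim = 48, emb_dim = 24, proj_dim = 12,
                                n_attributes = 7))) {
    set.seed(1)
    m <- gait_transformer(cfg)
    expect_equal(count_parameters(m),
                 cfg$n_layers * per_layer(cfg$d_model, cfg$ff_dim) +
                   fixed(cfg$d_model, cfg$max_len, cfg$emb_dim,
                         cfg$proj_dim, cfg$n_attributes))
  }
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  cfg <- model_config(n_layers = 2, d_model = 8, n_heads = 2, ff_dim = 12,
                      max_len = 6, emb_dim = 8, proj_dim = 4,
                      n_attributes = 5)
  m <- gait_transformer(cfg)
  tok <- array(rnorm(4 * 5 * 54), c(4, 5, 54))
  labels <- c(1, 2, 1, 2)
  y <- matrix(runif(20), 4, 5)
  lossfun <- function(params) {
    m2 <- m; m2$params <- params
    fw <- gait_forward(m2, tok)
    supcon_loss(fw$projection, labels, tau = 0.5) +
      0.5 * soft_bce(fw$attributes, y)
  }
  fw <- gait_forward(m, tok, cache = TRUE)
  sc <- supcon_loss(fw$projection, labels, tau = 0.5, grad = TRUE)
  pc <- pmin(pmax(fw$attributes, 1e-7), 1 - 1e-7)
  g <- gaitseq:::gait_backward(m, fw$cache,
                               list(d_proj = sc$grad,
                                    d_attr_logits = 0.5 * (pc - y) / length(y)))
  eps <- 1e-5
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("model config validates its invariants", {
  expect_error(model_config(d_model = 30, n_heads = 8))
  expect_equal(model_config("md")$n_layers, 8L)
  expect_equal(model_config("xl")$n_layers, 12L)
})
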