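test_that("normalize_frame centers the pelvis and scales by shoulder/torso", {
  lay <- joint_layout()
  f <- matrix(0, 18, 3)
  f[lay$l_hip, 1:2] <- c(9, 20); f[lay$r_hip, 1:2] <- c(11, 20)
  f[lay$l_shoulder, 1:2] <- c(9, 18); f[lay$r_shoulder, 1:2] <- c(11, 18)
  f[lay$neck, 1:2] <- c(10, 18)
  f[1, 1:2] <- c(11, 18)
  nf <- normalize_frame(f)
  expect_equal(unname(nf[1, 1:2]), c(0.5, -1.0))
  pelvis <- (nf[lay$l_hip, 1:2] + nf[lay$r_hip, 1:2]) / 2
  expect_equal(unname(pelvis), c(0, 0))
  expect_false(attr(nf, "degenerate"))
})

test_that("normalization invariants hold on random frames", {
  set.seed(101)
  lay <- joint_layout()
  for (i in 1:200) {
    f <- random_frame()
    nf <- normalize_frame(f)
    # pelvis at origin, unit shoulder span and torso height
    pelvis <- (nf[lay$l_hip, 1:2] + nf[lay$r_hip, 1:2]) / 2
    expect_equal(unname(pelvis), c(0, 0), tolerance = 1e-12)
    expect_equal(abs(nf[lay$r_shoulder, 1] - nf[lay$l_shoulder, 1]), 1,
                 tolerance = 1e-12)
    expect_equal(abs(nf[lay$neck, 2]), 1, tolerance = 1e-12)
    # idempotence
    expect_equal(unname(normalize_frame(nf)[, 1:2]), unname(nf[, 1:2]),
                 tolerance = 1e-12)
    # translation invariance
    g <- f; g[, 1] <- g[, 1] + 37.5; g[, 2] <- g[, 2] - 12.25
    expect_equal(unname(normalize_frame(g)[, 1:2]), unname(nf[, 1:2]),
                 tolerance = 1e-12)
    # scale invariance
    s <- f; s[, 1:2] <- s[, 1:2] * 3.7
    expect_equal(unname(normalize_frame(s)[, 1:2]), unname(nf[, 1:2]),
                 tolerance = 1e-12)
    # confidences bit-exact
    expect_identical(nf[, 3], f[, 3])
  }
})

test_that("degenerate frames are flagged, never divided by zero", {
  f <- matrix(1, 18, 3)          # all joints coincident
  f[, 3] <- 0.9
  nf <- normalize_frame(f)
  expect_true(attr(nf, "degenerate"))
  expect_true(all(is.finite(nf)))
})

test_that("normalize_sequence maps frames independently", {
  tr <- const_tracklet(10)
  seq <- normalize_sequence(tr)
  expect_s3_class(seq, "gait_sequence")
  expect_equal(dim(seq$data)[1], 10)
  # identical input frames give identical normalized frames
  for (t in 2:10) expect_equal(seq$data[t, , ], seq$data[1, , ])
  empty <- gait_tracklet(array(0, c(0, 18, 3)), fps = 24)
  expect_error(normalize_sequence(empty), "empty")
})

test_that("resampling preserves wall-clock duration and linear signals", {
  tr <- const_tracklet(100, fps = 48, drift = 0.5)
  r <- resample_tracklet(tr, 24)
  expect_equal(dim(r$data)[1], 50)
  expect_equal(r$fps, 24)
  # identity at the source fps
  tr24 <- const_tracklet(30, fps = 24, drift = 0.5)
  expect_identical(resample_tracklet(tr24, 24)$data, tr24$data)
  # linear motion survives a resample round trip (interior frames)
  back <- resample_tracklet(r, 48)
  n_cmp <- min(dim(back$data)[1], 100) - 1
  expect_equal(back$data[1:n_cmp, , 1:2], tr$data[1:n_cmp, , 1:2],
               tolerance = 1e-9)
  expect_error(resample_tracklet(gait_tracklet(array(0.5, c(1, 18, 3)), 24), 48),
               "2 frames")
})

test_that("center_crop takes the exact middle window", {
  dat <- array(0, c(100, 18, 3))
  dat[, 1, 1] <- seq_len(100)            # frame tag in the nose x channel
  s <- gait_sequence(dat)
  c48 <- center_crop(s, 48)
  expect_equal(c48$data[, 1, 1], 27:74)  # 0-based frames 26..73
  s49 <- gait_sequence(dat[1:49, , , drop = FALSE])
  expect_equal(center_crop(s49, 48)$data[, 1, 1], 1:48)  # 0-based 0..47
  expect_identical(center_crop(c48, 48)$data, c48$data)  # L = T
  expect_error(center_crop(s49, 50), "shorter")
})

test_that("flatten/unflatten is a bijection with 54-wide rows", {
  set.seed(7)
  dat <- array(rnorm(20 * 18 * 3), c(20, 18, 3))
  dat[, , 3] <- runif(20 * 18)
  s <- gait_sequence(dat)
  m <- flatten_sequence(s)
  expect_equal(dim(m), c(20, 54))
  expect_identical(unflatten_sequence(m)$data, s$data)
  # token layout: (x, y, c) triplets in joint order
  expect_identical(m[, 1], dat[, 1, 1])
  expect_identical(m[, 3], dat[, 1, 3])
  zero <- gait_sequence(array(0, c(1, 18, 3)))
  expect_equal(flatten_sequence(zero), matrix(0, 1, 54))
})

test_that("mean_leg_speed measures per-frame leg displacement", {
  tr <- const_tracklet(10)
  s <- gait_sequence(tr$data)
  expect_equal(mean_leg_speed(s), 0)
  # every leg joint moves exactly (0.003, 0) per frame
  lay <- joint_layout()
  dat <- array(0, c(5, 18, 3))
  for (t in 1:5) dat[t, lay$legs, 1] <- (t - 1) * 0.003
  expect_equal(mean_leg_speed(gait_sequence(dat)), 0.003)
  expect_error(mean_leg_speed(gait_sequence(dat[1, , , drop = FALSE])),
               "2 frames")
})
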