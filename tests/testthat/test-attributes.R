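test_that("the shipped schema is complete and well-formed", {
  sch <- attribute_schema()
  expect_length(sch$names, 42)
  expect_setequal(unique(sch$groups),
                  c("Gender", "AgeGroup", "BodyType", "Viewpoint",
                    "CarryConditions", "Clothing", "Footwear",
                    "ApparentAction"))
  expect_true(all(table(sch$groups) >= 1))
  # every source label maps to a known target or an explicit DROP
  for (src in names(sch$sources))
    expect_true(all(sch$sources[[src]] %in% c(sch$names, "DROP")))
  expect_true(all(sch$modes %in% c("average", "max")))
})

test_that("coalescing averages or maxes mapped source scores", {
  sch <- attribute_schema()
  # the child-age merge averages the two source scores: (0.8 + 0.6)/2
  out <- coalesce_attributes(list(
    pa100k = c(AgeLess18 = 0.8),
    rap = c(AgeLess16 = 0.6)), sch)
  expect_equal(unname(out["AgeChild"]), 0.7)
  expect_length(out, 42)
  # single-source targets pass through
  out2 <- coalesce_attributes(list(pa100k = c(LongCoat = 0.35)), sch)
  expect_equal(unname(out2["LongCoat"]), 0.35)
  # max-mode targets take the union
  out3 <- coalesce_attributes(list(
    peta = c(FormalUpper = 0.2, FormalLower = 0.6),
    rap = c(`Suit-Up` = 0.4)), sch)
  expect_equal(unname(out3["FormalWear"]), 0.6)
  # all-zero sources give all-zero output
  z <- coalesce_attributes(list(rap = stats::setNames(
    numeric(length(sch$sources$rap)), names(sch$sources$rap))), sch)
  expect_true(all(z == 0))
  # unmapped labels are an error
  expect_error(coalesce_attributes(list(pa100k = c(NotALabel = 1)), sch),
               "unmapped")
})

test_that("crop predictions are augmentation averages, robust to failures", {
  cfg <- annotation_config(k_augment = 4)
  const <- function(crop, aug) c(Female = 0.8)
  expect_equal(predict_crop(const, NULL, cfg), c(Female = 0.8))
  # zero-sum perturbations cancel in the mean
  deltas <- c(-0.2, -0.1, 0.1, 0.2); i <- 0
  wobble <- function(crop, aug) { i <<- i + 1; c(Female = 0.5 + deltas[i]) }
  expect_equal(predict_crop(wobble, NULL, cfg), c(Female = 0.5))
  # four copies 0.2 / 0.4 / 0.6 / 0.8 average to 0.5
  vals <- c(0.2, 0.4, 0.6, 0.8); j <- 0
  stepper <- function(crop, aug) { j <<- j + 1; c(Female = vals[j]) }
  expect_equal(predict_crop(stepper, NULL, cfg), c(Female = 0.5))
  # failing copies are skipped; total failure is an error
  k <- 0
  flaky <- function(crop, aug) {
    k <<- k + 1
    if (k < 4) stop("boom") else c(Female = 0.3)
  }
  expect_equal(predict_crop(flaky, NULL, cfg), c(Female = 0.3))
  broken <- function(crop, aug) stop("boom")
  expect_error(predict_crop(broken, NULL, cfg), "failed")
})

test_that("crops are sampled every period_T frames", {
  tr <- const_tracklet(100)
  tr$bbox <- cbind(1:100, 1:100, rep(50, 100), rep(100, 100))
  expect_equal(sample_crops(tr, 48)$frame, c(0, 48, 96))
  tr48 <- const_tracklet(48)
  tr48$bbox <- matrix(1, 48, 4)
  expect_equal(sample_crops(tr48, 48)$frame, 0)
  tr200 <- const_tracklet(200)
  tr200$bbox <- matrix(1, 200, 4)
  expect_equal(sample_crops(tr200, 48)$frame, c(0, 48, 96, 144, 192))
  expect_error(sample_crops(const_tracklet(10), 48), "bounding boxes")
})

test_that("sequence aggregation is an area-weighted convex combination", {
  # areas (0.3, 0.1): weights (0.75, 0.25) -> 0.75*0.8 + 0.25*0.4 = 0.7
  expect_equal(aggregate_tracklet(list(0.8, 0.4), c(0.3, 0.1)), 0.7)
  expect_equal(aggregate_tracklet(list(c(a = 0.2), c(a = 0.6)), c(1, 1)),
               c(a = 0.4))
  expect_equal(aggregate_tracklet(list(c(0.9)), 0.2), 0.9)
  expect_error(aggregate_tracklet(list(0.5, 0.5), c(0, 0)), "zero")
  # convexity, permutation equivariance, monotonicity toward heavier crops
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    preds <- replicate(k, runif(5), simplify = FALSE)
    areas <- runif(k, 0.01, 1)
    agg <- aggregate_tracklet(preds, areas)
    expect_true(all(agg >= 0 & agg <= 1))
    perm <- sample(k)
    expect_equal(aggregate_tracklet(preds[perm], areas[perm]), agg)
    heavier <- areas; heavier[1] <- heavier[1] * 3
    agg2 <- aggregate_tracklet(preds, heavier)
    # moving weight to crop 1 moves every entry toward crop 1's prediction
    expect_true(all(abs(agg2 - preds[[1]]) <= abs(agg - preds[[1]]) + 1e-12))
  }
})

test_that("full tracklet annotation yields 42 soft labels in [0,1]", {
  set.seed(3)
  tr <- render_tracklet(sample_walker(3)$params, 144, 24, seed = 4)
  sch <- attribute_schema()
  preds <- gaitseq:::mock_predictor_ensemble(sch, seed = 1)
  out <- annotate_tracklet(tr, preds, sch)
  expect_length(out, 42)
  expect_true(all(out >= 0 & out <= 1))
  expect_named(out, sch$names)
})
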