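# Training objective (BCE + Dice) and evaluation metrics.

test_that("binary cross-entropy matches direct evaluation", {
  expect_equal(bceLoss(matrix(1), matrix(0.5)), -log(0.5), tolerance = 1e-12)
  expect_equal(bceLoss(matrix(c(1, 0), 1), matrix(c(0.9, 0.1), 1)),
               -log(0.9), tolerance = 1e-12)
  # confidently correct prediction: bounded below by the clamp, ~0
  expect_lt(bceLoss(matrix(0), matrix(1e-12)), 1e-6)
  expect_gte(bceLoss(matrix(0), matrix(1e-12)), 0)
  # non-negative for random inputs
  y <- withr::with_seed(1, randMask(8, 8))
  p <- withr::with_seed(2, matrix(runif(64), 8, 8))
  expect_gte(bceLoss(y, p), 0)
  expect_error(bceLoss(matrix(1), matrix(c(.2, .3), 1)), "shape")
})

test_that("Dice loss matches direct evaluation and handles empty masks", {
  y <- withr::with_seed(3, randMask(6, 6, 0.4))
  expect_equal(diceLoss(y, y), 0, tolerance = 1e-12) # exact match
  # four foreground pixels, all missed: 1 - 1/5
  expect_equal(diceLoss(matrix(1, 2, 2), matrix(0, 2, 2)), 0.8,
               tolerance = 1e-12)
  # empty-empty: the smoothing constant gives exact zero
  expect_equal(diceLoss(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  # dice loss + smoothed dice coefficient = 1 by construction
  p <- withr::with_seed(4, matrix(runif(36), 6, 6))
  coef <- (2 * sum(y * p) + 1) / (sum(y) + sum(p) + 1)
  expect_equal(diceLoss(y, p) + coef, 1, tolerance = 1e-12)
})

test_that("combined loss is the sum of its terms and exposes ablations", {
  y <- withr::with_seed(5, randMask(8, 8))
  p <- withr::with_seed(6, matrix(runif(64, 0.01, 0.99), 8, 8))
  expect_equal(combinedLoss(y, p), bceLoss(y, p) + diceLoss(y, p),
               tolerance = 1e-12)
  expect_identical(combinedLoss(y, p, mode = "bce_only"), bceLoss(y, p))
  expect_identical(combinedLoss(y, p, mode = "dice_only"), diceLoss(y, p))
  # near-perfect confident prediction drives the loss to ~0
  yy <- matrix(c(1, 0, 1, 0), 2)
  expect_lt(combinedLoss(yy, abs(yy - 1e-7)), 1e-3)
})

test_that("confusion counts partition the pixels", {
  cc <- confusionCounts(matrix(c(1, 1, 0, 0), 1), matrix(c(1, 0, 1, 0), 1))
  expect_identical(unlist(cc), c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  y <- withr::with_seed(7, randMask(16, 16))
  expect_identical(unlist(confusionCounts(y, y))[c("fp", "fn")],
                   c(fp = 0L, fn = 0L))
  for (s in 1:10) {
    y <- withr::with_seed(s, randMask(16, 16, 0.3))
    p <- withr::with_seed(s + 100, randMask(16, 16, 0.6))
    cc <- confusionCounts(y, p)
    expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 256L)
  }
  expect_error(confusionCounts(matrix(0.5), matrix(1)), "binary")
})

test_that("metrics match direct evaluation of their formulas", {
  m <- metricsFromCounts(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m[["dice"]], 6 / 9, tolerance = 1e-12)
  expect_equal(m[["miou"]], 0.5 * (3 / 6 + 4 / 7), tolerance = 1e-12)
  expect_equal(m[["recall"]], 3 / 5, tolerance = 1e-12)
  expect_equal(m[["precision"]], 3 / 4, tolerance = 1e-12)
  # zero-denominator convention: agreeing empty masks score 1
  perfectEmpty <- metricsFromCounts(list(tp = 0, fp = 0, fn = 0, tn = 9))
  expect_true(all(perfectEmpty == 1))
})

test_that("F1 equals Dice for any binary confusion counts", {
  cases <- withr::with_seed(8, replicate(50, {
    as.list(setNames(rpois(4, 5), c("tp", "fp", "fn", "tn")))
  }, simplify = FALSE))
  cases <- c(cases, list(list(tp = 0, fp = 2, fn = 3, tn = 1),
                         list(tp = 0, fp = 0, fn = 3, tn = 1),
                         list(tp = 0, fp = 2, fn = 0, tn = 1),
                         list(tp = 0, fp = 0, fn = 0, tn = 4)))
  for (cc in cases) {
    m <- metricsFromCounts(cc)
    expect_equal(m[["f1"]], m[["dice"]], tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("metric symmetries hold", {
  for (s in 1:10) {
    y <- withr::with_seed(s, randMask(12, 12, 0.4))
    p <- withr::with_seed(s + 50, randMask(12, 12, 0.4))
    expect_equal(segmentationMetrics(y, p)[["dice"]],
                 segmentationMetrics(p, y)[["dice"]], tolerance = 1e-12)
    expect_equal(segmentationMetrics(y, p)[["precision"]],
                 segmentationMetrics(p, y)[["recall"]], tolerance = 1e-12)
  }
  # perfect prediction: all ones; disjoint non-empty masks: overlap
  # metrics all zero
  y <- matrix(0, 4, 4); y[1:2, ] <- 1
  expect_true(all(segmentationMetrics(y, y) == 1))
  p <- 1 - y
  m <- segmentationMetrics(y, p)
  expect_true(all(m[c("dice", "recall", "precision", "f1")] == 0))
})

test_that("metrics agree with the per-pixel oracle on random masks", {
  for (s in 1:200) {
    y <- withr::with_seed(s, randMask(16, 16, runif(1, 0.05, 0.95)))
    p <- withr::with_seed(s + 1000, randMask(16, 16, runif(1, 0.05, 0.95)))
    expect_equal(unname(segmentationMetrics(y, p)),
                 unname(oracleMetrics(y, p)), tolerance = 1e-12)
  }
})
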