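test_that("BCE loss matches closed forms and hand arithmetic", {
  expect_lt(bceLoss(array(c(1, 0), c(2, 1)), array(c(1, 0), c(2, 1))), 1e-6)
  expect_equal(bceLoss(matrix(0.5, 3, 3), matrix(rep_len(c(0, 1), 9), 3)),
               log(2), tolerance = 1e-12)
  expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)),
               0.5 * (-log(0.9) - log(0.8)), tolerance = 1e-12)  # 0.16425...
  expect_error(bceLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("soft-IoU loss matches its closed forms", {
  expect_equal(iouLoss(rep(1, 100), rep(1, 100)), 0)  # 1 - 101/101
  n <- 7
  expect_equal(iouLoss(rep(0, 20), c(rep(1, n), rep(0, 13))), n / (n + 1))
  expect_equal(iouLoss(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)  # 1 - 2/4
})

test_that("soft-IoU decreases monotonically as predictions move toward the mask", {
  set.seed(8)
  y <- matrix(rbinom(64, 1, 0.4), 8)
  p0 <- matrix(runif(64), 8)
  losses <- vapply(seq(0, 1, 0.1), function(a)
    iouLoss(p0 + a * (y - p0), y), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("IoU and Dice metrics: counting cases, symmetry, empty convention", {
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- a; b[1, 2] <- 1
  expect_equal(iouMetric(a, b), 0.5)
  expect_equal(diceMetric(a, b), 2 / 3)
  expect_equal(iouMetric(b, b), 1)
  d <- matrix(0, 4, 4); d[4, 4] <- 1
  expect_equal(iouMetric(a, d), 0)
  expect_equal(diceMetric(a, d), 0)
  z <- matrix(0, 4, 4)
  expect_equal(iouMetric(z, z), 1)  # both-empty convention
  expect_equal(diceMetric(z, z), 1)
  expect_equal(iouMetric(a, b), iouMetric(b, a))
  expect_equal(diceMetric(a, b), diceMetric(b, a))
})

test_that("Dice = 2 IoU / (1 + IoU) identity holds for random mask pairs", {
  set.seed(17)
  for (i in 1:200) {
    a <- matrix(rbinom(36, 1, runif(1)), 6)
    b <- matrix(rbinom(36, 1, runif(1)), 6)
    iou <- iouMetric(a, b)
    expect_equal(diceMetric(a, b), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("augmentation transforms image and mask identically, metadata untouched", {
  s <- generateSample(generatorConfig(imageSize = 32L, seed = 6L), 1)
  withr::with_seed(1, {
    for (i in 1:25) {
      a <- augmentPair(s)
      expect_equal(a@metadata, s@metadata)
      expect_true(all(a@mask %in% c(0, 1)))
      expect_equal(sum(a@mask) > 0, TRUE)
      # lesion support of the transformed image tracks the transformed mask:
      # dark pixels (well below background) should lie mostly inside it
      gray <- apply(a@image, c(1, 2), mean)
      dark <- gray < quantile(gray, 0.1)
      expect_gt(mean(a@mask[dark]), 0.8)
    }
  })
  # an explicit flip is its own inverse and preserved pairing exactly
  flip <- function(m) m[, ncol(m):1]
  af <- withr::with_seed(42, replicate(40, augmentPair(s), simplify = FALSE))
  hit <- Filter(function(a) identical(a@mask, flip(s@mask)), af)
  expect_gt(length(hit), 0)
  expect_equal(hit[[1]]@image[, , 2], flip(s@image[, , 2]))
})

test_that("training is deterministic, checkpoints the best epoch and honours patience", {
  co <- easyCohort()
  tr <- co$samples[co$split@train][1:20]
  va <- co$samples[co$split@val]
  cfg <- modelConfig(inputSize = 32L, encoderWidths = c(8L), bottleneckWidth = 16L,
                     nPool = 2L, fusionStrategy = "none")
  tc <- trainConfig(learningRate = 1e-3, batchSize = 8L, maxEpochs = 4L,
                    earlyStopPatience = 4L, loss = "iou", seed = 5L)
  m <- buildModel(cfg, seed = 5)
  r1 <- trainModel(m, tr, va, tc)
  r2 <- trainModel(m, tr, va, tc)
  expect_identical(r1$history, r2$history)        # bit-reproducible
  expect_identical(r1$model@weights, r2$model@weights)
  # checkpoint: re-evaluating the returned weights gives the recorded minimum
  ev <- LesionSegUQ:::evalLossIoU(r1$model, va, "iou", 8L)
  expect_equal(ev$loss, min(r1$history$valLoss), tolerance = 1e-12)

  # patience 0: stop at the first epoch that fails to improve
  tc0 <- trainConfig(learningRate = 1e-3, batchSize = 8L, maxEpochs = 50L,
                     earlyStopPatience = 0L, loss = "iou", seed = 5L)
  r0 <- trainModel(m, tr, va, tc0)
  best <- which.min(r0$history$valLoss)
  expect_equal(nrow(r0$history), best + 1L)
})

test_that("augmented training accepts paired transforms end to end", {
  co <- easyCohort()
  tr <- co$samples[co$split@train][1:12]
  va <- co$samples[co$split@val][1:4]
  cfg <- modelConfig(inputSize = 32L, encoderWidths = c(8L), bottleneckWidth = 16L,
                     nPool = 2L, fusionStrategy = "none")
  tc <- trainConfig(learningRate = 1e-3, batchSize = 6L, maxEpochs = 2L,
                    earlyStopPatience = 2L, loss = "bce", augment = TRUE,
                    seed = 3L)
  r <- trainModel(buildModel(cfg, seed = 3), tr, va, tc)
  expect_equal(nrow(r$history), 2L)
  expect_true(all(is.finite(r$history$trainLoss)))
})
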