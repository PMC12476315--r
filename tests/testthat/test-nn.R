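# Engine-level checks of the forward/backward passes.

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  sch <- tinySchema()
  cfg <- modelConfig(inputSize = 8L, encoderWidths = c(3L), bottleneckWidth = 5L,
                     nPool = 2L, metadataWidth = 5L, embedDim = 2L,
                     fusionStrategy = "embedding_concat", bayesian = FALSE)
  m <- buildModel(cfg, sch, seed = 7)
  N <- 2L
  x <- array(runif(8 * 8 * 3 * N), c(8, 8, 3, N))
  y <- array(rbinom(8 * 8 * N, 1, 0.4), c(8, 8, 1, N))
  meta <- rbind(c(1, 0, 0, 1, 0), c(0, 0, 1, 0, 1))
  lossOf <- function(model, loss) {
    fw <- LesionSegUQ:::nnForward(model, x, meta, keepCache = TRUE)
    LesionSegUQ:::lossAndGrad(fw$probs, y, loss)
  }
  for (loss in c("bce", "iou")) {
    fw <- LesionSegUQ:::nnForward(m, x, meta, keepCache = TRUE)
    lg <- LesionSegUQ:::lossAndGrad(fw$probs, y, loss)
    g <- LesionSegUQ:::nnBackward(m, fw$cache, lg$dZ)
    h <- 1e-5
    for (nm in c("enc1.conv1", "bott.conv2", "dec1.up", "dec1.conv1",
                 "meta.dense1", "out")) {
      k <- sample(length(m@weights[[nm]]$W), 2L)
      for (kk in k) {
        m2 <- m
        m2@weights[[nm]]$W[kk] <- m@weights[[nm]]$W[kk] + h
        Lp <- lossOf(m2, loss)$loss
        m2@weights[[nm]]$W[kk] <- m@weights[[nm]]$W[kk] - h
        Lm <- lossOf(m2, loss)$loss
        num <- (Lp - Lm) / (2 * h)
        expect_lt(abs(num - g[[nm]]$W[kk]) /
                    max(1e-8, abs(num) + abs(g[[nm]]$W[kk])), 1e-4)
      }
    }
    # an embedding table row
    nm <- "embed.diagnosis"
    kk <- sample(length(m@weights[[nm]]), 1L)
    m2 <- m
    m2@weights[[nm]][kk] <- m@weights[[nm]][kk] + h
    Lp <- lossOf(m2, loss)$loss
    m2@weights[[nm]][kk] <- m@weights[[nm]][kk] - h
    Lm <- lossOf(m2, loss)$loss
    num <- (Lp - Lm) / (2 * h)
    expect_lt(abs(num - g[[nm]][kk]) / max(1e-8, abs(num) + abs(g[[nm]][kk])),
              1e-4)
  }
})

test_that("forward pass yields the declared output shape for varied configs", {
  set.seed(1)
  cfgs <- list(
    modelConfig(inputSize = 16L, encoderWidths = c(4L), bottleneckWidth = 8L,
                nPool = 1L, fusionStrategy = "none"),
    modelConfig(inputSize = 16L, encoderWidths = c(4L), bottleneckWidth = 8L,
                nPool = 2L, fusionStrategy = "onehot_dense"),
    modelConfig(inputSize = 32L, encoderWidths = c(4L, 8L), bottleneckWidth = 16L,
                nPool = 3L, fusionStrategy = "weighted",
                fusionWeights = c(0.7, 0.3)),
    modelConfig(inputSize = 32L, encoderWidths = c(4L, 8L), bottleneckWidth = 16L,
                nPool = 2L, fusionStrategy = "embedding_concat",
                bayesian = TRUE, dropoutRate = 0.3))
  sch <- defaultMetadataSchema()
  meta <- matrix(0, 2, 29)
  idx <- LesionSegUQ:::schemaGroupIndex(sch)
  for (g in sch@groups)
    if (g$type == "onehot") meta[, idx[[g$name]][1]] <- 1
  for (cfg in cfgs) {
    m <- buildModel(cfg, sch, seed = 3)
    S <- cfg@inputSize
    x <- array(runif(S * S * 3 * 2), c(S, S, 3, 2))
    fw <- LesionSegUQ:::nnForward(m, x, meta, stochastic = TRUE)
    expect_equal(dim(fw$probs), c(S, S, 1L, 2L))
    expect_true(all(fw$probs > 0 & fw$probs < 1))  # sigmoid range
  }
})

test_that("weighted(1,0) fusion reproduces the image-only network exactly", {
  set.seed(2)
  sch <- defaultMetadataSchema()
  cfgW <- modelConfig(inputSize = 16L, encoderWidths = c(4L), bottleneckWidth = 8L,
                      nPool = 1L, fusionStrategy = "weighted",
                      fusionWeights = c(1, 0))
  m <- buildModel(cfgW, sch, seed = 5)
  m0 <- m
  m0@config@fusionStrategy <- "none"  # same backbone weights, no metadata path
  meta <- matrix(0, 1, 29)
  idx <- LesionSegUQ:::schemaGroupIndex(sch)
  for (g in sch@groups)
    if (g$type == "onehot") meta[, idx[[g$name]][1]] <- 1
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  pw <- LesionSegUQ:::nnForward(m, x, meta)$probs
  p0 <- LesionSegUQ:::nnForward(m0, x, NULL)$probs
  expect_identical(pw, p0)
})

test_that("dropout at rate zero equals the deterministic forward pass", {
  set.seed(3)
  cfg <- tinyModelConfig("none", bayesian = TRUE, dropoutRate = 0)
  m <- buildModel(cfg, seed = 4)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  pDet <- LesionSegUQ:::nnForward(m, x, NULL, stochastic = FALSE)$probs
  pSto <- LesionSegUQ:::nnForward(m, x, NULL, stochastic = TRUE)$probs
  expect_identical(pDet, pSto)
})
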