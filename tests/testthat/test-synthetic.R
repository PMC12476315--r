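sch <- defaultMetadataSchema()

# Metadata vector with every renderable attribute absent.
allAbsentMeta <- function() {
  m <- numeric(29)
  idx <- LesionSegUQ:::schemaGroupIndex(sch)
  m[idx$diagnosis[1]] <- 1        # common nevus
  m[idx$asymmetry[1]] <- 1        # symmetric
  m[idx$pigment_network[1]] <- 1  # absent
  m[idx$dots_globules[1]] <- 1
  m[idx$streaks[1]] <- 1
  m[idx$regression[1]] <- 1
  m[idx$blue_whitish_veil[1]] <- 1
  m[idx$border_irregularity[1]] <- 1
  m
}

test_that("generation is bitwise deterministic and order-independent", {
  cfg <- generatorConfig(imageSize = 32L, nSamples = 5L, seed = 77L)
  a <- generateSample(cfg, 3)
  b <- generateSample(cfg, 3)
  expect_identical(a, b)
  ds <- generateDataset(cfg)
  expect_identical(ds[[3]], a)  # sample stream independent of order
})

test_that("generateDataset writes the full on-disk layout and a manifest that regenerates it", {
  dir <- withr::local_tempdir()
  cfg <- generatorConfig(imageSize = 32L, nSamples = 8L, seed = 13L)
  ds <- generateDataset(cfg, dir = dir)
  expect_length(ds, 8L)
  expect_length(list.files(file.path(dir, "images")), 8L)
  expect_length(list.files(file.path(dir, "masks")), 8L)
  md <- read.csv(file.path(dir, "metadata.csv"), check.names = FALSE)
  expect_equal(dim(md), c(8L, 30L))
  cfg2 <- generatorConfigFromManifest(file.path(dir, "manifest.yaml"))
  expect_identical(generateDataset(cfg2), ds)
})

test_that("toggling the streaks attribute only perturbs pixels in the spoke support", {
  cfg <- generatorConfig(imageSize = 48L, seed = 5L, sigmaN = 0)
  idx <- LesionSegUQ:::schemaGroupIndex(sch)
  m0 <- allAbsentMeta()
  m1 <- m0
  m1[idx$streaks[1]] <- 0; m1[idx$streaks[2]] <- 1  # regular streaks
  s0 <- generateSample(cfg, 2, metadata = m0)
  r1 <- generateSample(cfg, 2, metadata = m1, details = TRUE)
  expect_true("streaks" %in% names(r1$supports))
  diff <- apply(abs(r1$sample@image - s0@image), c(1, 2), max) > 1e-12
  expect_true(any(diff))
  expect_true(all(r1$supports$streaks[diff]))
  expect_identical(r1$sample@mask, s0@mask)  # overlays never alter the mask
})

test_that("rendered overlays match the metadata one-hot flags exactly", {
  cfg <- generatorConfig(imageSize = 32L, nSamples = 12L, seed = 31L)
  idx <- LesionSegUQ:::schemaGroupIndex(sch)
  for (i in 1:12) {
    r <- generateSample(cfg, i, details = TRUE)
    m <- r$sample@metadata
    expect_equal("pigment_network" %in% names(r$supports),
                 m[idx$pigment_network[1]] == 0)
    expect_equal("streaks" %in% names(r$supports), m[idx$streaks[1]] == 0)
    expect_equal("dots_globules" %in% names(r$supports),
                 m[idx$dots_globules[1]] == 0)
    expect_equal("blue_whitish_veil" %in% names(r$supports),
                 m[idx$blue_whitish_veil[2]] == 1)
  }
})

test_that("a noise-free full-contrast render is exactly recovered by Otsu thresholding", {
  cfg <- generatorConfig(imageSize = 64L, sigmaB = 0, sigmaN = 0, contrast = 1,
                         seed = 9L)
  s <- generateSample(cfg, 1, metadata = allAbsentMeta())
  gray <- apply(s@image, c(1, 2), mean)
  th <- LesionSegUQ:::otsuThreshold(gray)
  rec <- (gray < th) + 0  # lesion is dark
  expect_equal(iouMetric(rec, s@mask), 1.0)
})

test_that("increasing boundary blur decreases the mean edge gradient", {
  meanEdgeGrad <- function(sigmaB) {
    g <- numeric(20)
    for (seed in 1:20) {
      cfg <- generatorConfig(imageSize = 48L, sigmaB = sigmaB, sigmaN = 0,
                             seed = seed)
      s <- generateSample(cfg, 1, metadata = allAbsentMeta())
      gray <- apply(s@image, c(1, 2), mean)
      gx <- gray[-1, ] - gray[-nrow(gray), ]
      gy <- gray[, -1] - gray[, -ncol(gray)]
      mag <- sqrt(gx[, -1]^2 + gy[-1, ]^2)
      edge <- s@mask[-1, -1] != s@mask[-nrow(s@mask), -ncol(s@mask)]
      edge <- edge | (s@mask[-1, -1] != s@mask[-1, -ncol(s@mask)])
      g[seed] <- mean(mag[edge])
    }
    mean(g)
  }
  grads <- vapply(c(0.5, 1.5, 3), meanEdgeGrad, numeric(1))
  expect_true(all(diff(grads) < 0))
})

test_that("attribute prevalences hit their binomial targets", {
  cfg <- generatorConfig(imageSize = 16L, nSamples = 400L, seed = 101L,
                         lesionFracRange = c(0.5, 0.7))
  mel <- LesionSegUQ:::schemaGroupIndex(sch)$diagnosis[3]
  meta <- vapply(seq_len(400), function(i)
    generateSample(cfg, i)@metadata[mel], numeric(1))
  p <- defaultPrevalence()$diagnosis[3]  # 0.3
  bound <- 3 * sqrt(p * (1 - p) / 400)
  expect_lt(abs(mean(meta) - p), bound)
})

test_that("the ambiguous task is resolvable by metadata but not by intensity alone", {
  cfg <- makeAmbiguousTask(generatorConfig(imageSize = 32L, seed = 55L))
  expect_lte(cfg@contrast, 0.15)
  expect_true(cfg@polarityByDiagnosis)
  mel <- LesionSegUQ:::schemaGroupIndex(sch)$diagnosis[3]
  # Pixel-level discriminants: the metadata-aware rule thresholds on the
  # correct side of the background level; the image-only rule can only use
  # the two-sided deviation |I - mu_bg| since lesion polarity is a latent
  # 50/50 mixture. Both thresholds are chosen optimally on held-out pixels.
  iouMeta <- iouImg <- numeric(30)
  for (i in 1:30) {
    s <- generateSample(cfg, i)
    gray <- apply(s@image, c(1, 2), mean)
    mu <- median(gray[s@mask == 0])
    dev <- gray - mu
    melanoma <- s@mask * 0 + s@metadata[mel]
    signDev <- if (s@metadata[mel] == 1) -dev else dev
    bestIoU <- function(score) {
      max(vapply(quantile(score, seq(0.3, 0.95, 0.05)), function(t)
        iouMetric((score > t) + 0, s@mask), numeric(1)))
    }
    iouMeta[i] <- bestIoU(signDev)
    iouImg[i] <- bestIoU(abs(dev))
  }
  expect_gt(mean(iouMeta), mean(iouImg))
})

test_that("degenerate lesions trigger resampling rather than empty masks", {
  cfg <- generatorConfig(imageSize = 32L, seed = 2L)
  for (i in 1:10) expect_gte(sum(generateSample(cfg, i)@mask), 9)
})

test_that("high-contrast passthrough keeps the polarity rule inert", {
  cfg <- makeAmbiguousTask(generatorConfig(imageSize = 32L, seed = 7L))
  cfg@contrast <- 1
  s <- generateSample(cfg, 1, metadata = allAbsentMeta())  # non-melanoma
  gray <- apply(s@image, c(1, 2), mean)
  # lesion is clearly separable (lighter for non-melanoma at c = 1)
  expect_gt(mean(gray[s@mask == 1]), mean(gray[s@mask == 0]))
  th <- LesionSegUQ:::otsuThreshold(gray)
  expect_gt(iouMetric((gray > th) + 0, s@mask), 0.8)
})
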