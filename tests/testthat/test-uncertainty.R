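test_that("vectorized maps equal the naive per-pixel loops within 1e-10", {
  for (seed in 1:4) {
    T <- sample(2:5, 1)
    ens <- randomEnsemble(T, 8L, 8L, seed)
    ref <- naiveMaps(ens)
    expect_lt(max(abs(confidenceMap(ens) - ref$C)), 1e-10)
    expect_lt(max(abs(entropyMap(ens) - ref$H)), 1e-10)
    expect_lt(max(abs(mutualInformationMap(ens) - ref$MI)), 1e-10)
    expect_lt(max(abs(epklMap(ens) - ref$EPKL)), 1e-10)
  }
})

test_that("analytic examples of the four estimators", {
  # confidence: averaging then max
  ens <- constantEnsemble(list(c(0.9, 0.1), c(0.5, 0.5)))
  expect_equal(confidenceMap(ens)[1, 1], 0.7)
  expect_equal(confidenceMap(constantEnsemble(list(c(0.5, 0.5))))[1, 1], 0.5)
  # entropy in bits
  expect_equal(entropyMap(constantEnsemble(list(c(0.5, 0.5))))[1, 1], 1.0)
  expect_equal(entropyMap(constantEnsemble(list(c(1, 0))))[1, 1], 0,
               tolerance = 1e-10)
  expect_equal(entropyMap(constantEnsemble(list(c(0.9, 0.1))))[1, 1],
               -0.9 * log2(0.9) - 0.1 * log2(0.1), tolerance = 1e-12)  # 0.4690
  # mutual information
  same <- constantEnsemble(list(c(0.8, 0.2), c(0.8, 0.2), c(0.8, 0.2)))
  expect_equal(mutualInformationMap(same)[1, 1], 0, tolerance = 1e-10)
  expect_equal(mutualInformationMap(
    constantEnsemble(list(c(1, 0), c(0, 1))))[1, 1], 1.0, tolerance = 1e-6)
  # EPKL: zero under agreement, symmetric-KL hand value, permutation symmetry
  expect_equal(epklMap(same)[1, 1], 0, tolerance = 1e-10)
  ens2 <- constantEnsemble(list(c(0.9, 0.1), c(0.1, 0.9)))
  expect_equal(epklMap(ens2)[1, 1], 0.8 * log2(9), tolerance = 1e-10)  # 2.5359
  ens2r <- constantEnsemble(list(c(0.1, 0.9), c(0.9, 0.1)))
  expect_equal(epklMap(ens2), epklMap(ens2r))
  expect_error(epklMap(constantEnsemble(list(c(0.5, 0.5)))), "T >= 2")
})

test_that("the mean-variant EPKL matches its own definition oracle", {
  ens <- randomEnsemble(4L, 5L, 5L, 99)
  P <- ens@probs
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    pbar <- c(mean(P[, i, j, 1]), mean(P[, i, j, 2]))
    ref[i, j] <- mean(vapply(1:4, function(t)
      sum(P[t, i, j, ] * (log2(pmax(P[t, i, j, ], 1e-12)) -
                            log2(pmax(pbar, 1e-12)))), numeric(1)))
  }
  expect_lt(max(abs(epklMap(ens, variant = "mean") - ref)), 1e-10)
})

test_that("pixelwise uncertainty invariants hold on random ensembles", {
  for (seed in 5:8) {
    ens <- randomEnsemble(4L, 8L, 8L, seed)
    H <- entropyMap(ens); MI <- mutualInformationMap(ens)
    C <- confidenceMap(ens)
    expect_true(all(MI >= -1e-10))
    expect_true(all(MI <= H + 1e-10))
    expect_true(all(H <= 1 + 1e-12))  # log2(2 classes)
    expect_true(all(C >= 0.5 - 1e-12 & C <= 1 + 1e-12))
    # binary consistency: H is the binary entropy of the max-class prob
    hOfC <- -C * log2(pmax(C, 1e-12)) - (1 - C) * log2(pmax(1 - C, 1e-12))
    expect_lt(max(abs(H - hOfC)), 1e-10)
    expect_true(all(epklMap(ens) >= -1e-10))
  }
})

test_that("mcdPredict demands a Bayesian model and is seed-deterministic", {
  co <- easyCohort()
  s <- co$samples[[1]]
  mPlain <- buildModel(tinyModelConfig("none", bayesian = FALSE), seed = 1)
  expect_error(mcdPredict(mPlain, s), "bayesian = TRUE")
  m <- buildModel(tinyModelConfig("none", bayesian = TRUE, dropoutRate = 0.25),
                  seed = 1)
  e1 <- mcdPredict(m, s, T = 4L, seed = 9L)
  e2 <- mcdPredict(m, s, T = 4L, seed = 9L)
  expect_identical(e1@probs, e2@probs)
  expect_equal(dim(mcdPredict(m, s, seed = 1L)@probs)[1], 10L)  # default T
  # distinct passes actually disagree somewhere at rate > 0
  expect_gt(max(abs(e1@probs[1, , , 1] - e1@probs[2, , , 1])), 0)
  # rate 0: all passes identical
  m0 <- buildModel(tinyModelConfig("none", bayesian = TRUE, dropoutRate = 0),
                   seed = 1)
  e0 <- mcdPredict(m0, s, T = 5L, seed = 2L)
  for (t in 2:5) expect_identical(e0@probs[t, , , ], e0@probs[1, , , ])
})

test_that("cohort normalization, aggregate score and ranking follow the rules", {
  mkReport <- function(id, means) {
    new("UncertaintyReport", id = id, maps = list(), means = means,
        normalized = c(C = NA_real_, H = NA_real_, MI = NA_real_,
                       EPKL = NA_real_),
        uTot = NA_real_, weights = c(0.4, 0.2, 0.2, 0.2),
        cohort = NA_character_)
  }
  means <- function(v) c(C = v, H = v, MI = v, EPKL = v)
  reps <- normalizeMeasures(list(mkReport("a", means(0.1)),
                                 mkReport("b", means(0.2)),
                                 mkReport("c", means(0.3))))
  expect_equal(vapply(reps, function(r) r@normalized[["C"]], numeric(1)),
               c(0, 0.5, 1))
  # with all four measures equal the score is 0.4x - 0.2x + 0.2x - 0.2x = 0.2x
  expect_equal(vapply(reps, function(r) r@uTot, numeric(1)),
               0.2 * c(0, 0.5, 1))
  # single-image and constant cohorts normalize to zero
  one <- normalizeMeasures(list(mkReport("solo", means(0.7))))
  expect_equal(unname(one[[1]]@normalized), rep(0, 4))
  const <- normalizeMeasures(list(mkReport("a", means(0.4)),
                                  mkReport("b", means(0.4))))
  expect_equal(unname(const[[2]]@normalized), rep(0, 4))
  expect_error(normalizeMeasures(list()), "empty")

  # aggregate score arithmetic and weight validation
  expect_equal(aggregateScore(1, 0, 0, 0), 0.4)
  expect_equal(aggregateScore(0.5, 0.5, 0.5, 0.5), 0.1)
  expect_equal(aggregateScore(0, 1, 0, 1), -0.4)
  expect_error(aggregateScore(0.5, 0.5, 0.5, 0.5, weights = c(0.4, -0.2, 0.2, 0.2)),
               "non-negative")

  # ranking: descending scores, lexicographic ties, top-k, cohort guard
  r3 <- normalizeMeasures(list(
    mkReport("a", c(C = 0.9, H = 0.1, MI = 0.1, EPKL = 0.1)),
    mkReport("b", c(C = 0.1, H = 0.9, MI = 0.9, EPKL = 0.9)),
    mkReport("c", c(C = 0.5, H = 0.5, MI = 0.5, EPKL = 0.5))))
  expect_equal(rankByUncertainty(r3), c("a", "c", "b"))
  tie <- normalizeMeasures(list(mkReport("z", means(0.5)),
                                mkReport("y", means(0.5))))
  expect_equal(rankByUncertainty(tie), c("y", "z"))
  big <- normalizeMeasures(lapply(1:50, function(i)
    mkReport(sprintf("im%02d", i), means(runif(1)))))
  expect_length(rankByUncertainty(big, k = 5), 5L)
  mixed <- c(r3[1:2], tie[1])
  expect_error(rankByUncertainty(mixed), "cohort")
})

test_that("uncertainty outputs are written as TIFF + PNG + CSV and round-trip", {
  ens <- randomEnsemble(3L, 6L, 6L, 21)
  reps <- normalizeMeasures(list(uncertaintyReport(ens)))
  dir <- withr::local_tempdir()
  df <- writeUncertaintyOutputs(reps, dir)
  expect_true(file.exists(file.path(dir, "ens21_EPKL.tif")))
  expect_true(file.exists(file.path(dir, "ens21_C.png")))
  tif <- EBImage::readImage(file.path(dir, "ens21_H.tif"))
  expect_equal(t(EBImage::imageData(tif)), reps[[1]]@maps$H, tolerance = 1e-6)
  back <- read.csv(file.path(dir, "uncertainty_summary.csv"))
  expect_equal(back$meanC, reps[[1]]@means[["C"]], tolerance = 1e-6)
})
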