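# Shared fixtures. Everything is generated in code at test time; the cache
# avoids regenerating the same synthetic cohorts across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small two-group schema for fast network tests (width 5).
tinySchema <- function() {
  metadataSchema(list(
    list(name = "diagnosis", type = "onehot", categories = c("a", "b", "c")),
    list(name = "flags", type = "binary", categories = c("f1", "f2"))))
}

# Small trainable U-Net configuration for 32 px synthetic images.
tinyModelConfig <- function(strategy = "none", bayesian = FALSE,
                            dropoutRate = 0.25) {
  modelConfig(inputSize = 32L, encoderWidths = c(16L, 32L),
              bottleneckWidth = 64L, nPool = 2L, fusionStrategy = strategy,
              bayesian = bayesian, dropoutRate = dropoutRate)
}

# 90-sample easy synthetic cohort at 32 px, split 70:10:20.
easyCohort <- function() {
  fixture("easyCohort", function() {
    cfg <- generatorConfig(imageSize = 32L, nSamples = 90L, seed = 11L)
    samples <- generateDataset(cfg)
    ids <- vapply(samples, function(s) s@id, character(1))
    list(samples = stats::setNames(samples, ids), cfg = cfg,
         split = splitDataset(ids, seed = 11L))
  })
}

# Random T x H x W x 2 ensembles for the uncertainty-math oracles.
randomEnsemble <- function(T, H, W, seed) {
  p <- withr::with_seed(seed, array(stats::runif(T * H * W), c(T, H, W, 1L)))
  probs <- array(0, c(T, H, W, 2L))
  probs[, , , 1L] <- p
  probs[, , , 2L] <- 1 - p
  new("PredictionEnsemble", probs = probs, id = sprintf("ens%d", seed),
      seed = as.integer(seed))
}

# Naive per-pixel reference implementations of the four uncertainty
# estimators, written directly from their definitions (independent of the
# vectorized production code paths).
naiveMaps <- function(ensemble) {
  P <- ensemble@probs
  T <- dim(P)[1]; H <- dim(P)[2]; W <- dim(P)[3]
  ent <- function(p) sum(-p * log2(pmax(p, 1e-12)))
  C <- Hm <- MI <- EPKL <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      pbar <- c(mean(P[, i, j, 1]), mean(P[, i, j, 2]))
      C[i, j] <- max(pbar)
      Hm[i, j] <- ent(pbar)
      MI[i, j] <- Hm[i, j] - mean(vapply(seq_len(T), function(t)
        ent(P[t, i, j, ]), numeric(1)))
      acc <- 0
      for (a in seq_len(T)) for (b in seq_len(T)) if (a != b) {
        pa <- pmax(P[a, i, j, ], 1e-12); pb <- pmax(P[b, i, j, ], 1e-12)
        acc <- acc + sum(P[a, i, j, ] * (log2(pa) - log2(pb)))
      }
      EPKL[i, j] <- acc / (T * (T - 1))
    }
  }
  list(C = C, H = Hm, MI = MI, EPKL = EPKL)
}

# Build an ensemble from an explicit list of per-pass binary distributions
# applied uniformly over a 2 x 2 image (for the analytic examples).
constantEnsemble <- function(passes) {
  T <- length(passes)
  probs <- array(0, c(T, 2L, 2L, 2L))
  for (t in seq_len(T)) {
    probs[t, , , 1L] <- passes[[t]][1]
    probs[t, , , 2L] <- passes[[t]][2]
  }
  new("PredictionEnsemble", probs = probs, id = "const", seed = 0L)
}
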