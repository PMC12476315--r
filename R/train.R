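#' Configure training
#'
#' @param learningRate,batchSize,maxEpochs,earlyStopPatience,loss,augment,seed
#'   see [TrainConfig-class].
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 16L, maxEpochs = 200L,
                        earlyStopPatience = 20L, loss = "iou",
                        augment = FALSE, seed = 1L) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      earlyStopPatience = as.integer(earlyStopPatience), loss = loss,
      augment = augment, seed = as.integer(seed))
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels of `-(y log p + (1 - y) log(1 - p))` with
#' probabilities clipped at `1e-7`.
#'
#' @param predProbs predicted probabilities in `(0, 1)` (any array shape).
#' @param mask ground-truth 0/1 labels of the same shape.
#' @return scalar loss.
#' @examples
#' bceLoss(array(0.5, c(2, 2)), array(1, c(2, 2)))  # log(2)
#' @export
bceLoss <- function(predProbs, mask) {
  if (!all(dim(predProbs) == dim(mask)) ||
      length(predProbs) != length(mask))
    stop("prediction and mask shapes differ")
  eps <- 1e-7
  p <- pmin(pmax(predProbs, eps), 1 - eps)
  mean(-(mask * log(p) + (1 - mask) * log(1 - p)))
}

#' Soft-IoU (Jaccard) loss
#'
#' The differentiable Jaccard surrogate
#' `1 - (sum(p * y) + eps) / (sum(p) + sum(y) - sum(p * y) + eps)` with
#' smoothing `eps = 1`.
#'
#' @inheritParams bceLoss
#' @return scalar loss.
#' @examples
#' iouLoss(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1 - 2/4 = 0.5
#' @export
iouLoss <- function(predProbs, mask) {
  if (length(predProbs) != length(mask)) stop("prediction and mask shapes differ")
  eps <- 1
  i <- sum(predProbs * mask)
  u <- sum(predProbs) + sum(mask) - i
  1 - (i + eps) / (u + eps)
}

# Loss value plus gradient w.r.t. the pre-sigmoid output, batched
# [H, W, 1, N]. Soft-IoU is computed per sample and averaged.
lossAndGrad <- function(probs, y, loss) {
  N <- dim(probs)[4]
  if (loss == "bce") {
    eps <- 1e-7
    p <- pmin(pmax(probs, eps), 1 - eps)
    L <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    dZ <- (probs - y) / length(probs)
    return(list(loss = L, dZ = dZ))
  }
  eps <- 1
  dZ <- array(0, dim(probs))
  Ls <- numeric(N)
  for (n in seq_len(N)) {
    p <- probs[, , 1L, n]; yn <- y[, , 1L, n]
    i <- sum(p * yn); u <- sum(p) + sum(yn) - i
    Ls[n] <- 1 - (i + eps) / (u + eps)
    dLdp <- -(yn * (u + eps) - (i + eps) * (1 - yn)) / (u + eps)^2 / N
    dZ[, , 1L, n] <- dLdp * p * (1 - p)
  }
  list(loss = mean(Ls), dZ = dZ)
}

#' IoU and Dice overlap metrics between binary masks
#'
#' Predictions are binarized at 0.5. When both masks are empty the metrics
#' are 1 (a correct empty prediction).
#'
#' @param predMask predicted mask (probabilities allowed; thresholded at
#'   0.5).
#' @param gtMask ground-truth 0/1 mask of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
iouMetric <- function(predMask, gtMask) {
  a <- predMask >= 0.5; b <- gtMask >= 0.5
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' @rdname iouMetric
#' @export
diceMetric <- function(predMask, gtMask) {
  a <- predMask >= 0.5; b <- gtMask >= 0.5
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

applyGeom <- function(m, op, scaleFactor = 1, bilinear = TRUE, fill = 0) {
  switch(op,
    identity = m,
    hflip = m[, ncol(m):1, drop = FALSE],
    vflip = m[nrow(m):1, , drop = FALSE],
    rot90 = rot90cw(m),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = rot90cw(rot90cw(rot90cw(m))),
    scale = {
      S <- nrow(m)
      S2 <- max(4L, round(S * scaleFactor))
      r <- ebResizeGray(m, S2, S2, bilinear = bilinear)
      if (S2 >= S) {
        off <- (S2 - S) %/% 2
        r[off + seq_len(S), off + seq_len(S), drop = FALSE]
      } else {
        out <- matrix(fill, S, S)
        off <- (S - S2) %/% 2
        out[off + seq_len(S2), off + seq_len(S2)] <- r
        out
      }
    })
}

#' Paired geometric augmentation of a sample
#'
#' Draws one transform (identity, horizontal/vertical flip, rotation by
#' 90/180/270 degrees, or scaling in `[0.9, 1.1]` with centre crop/pad) and
#' applies it identically to image and mask; the mask stays binary
#' (nearest-neighbour scaling). The metadata vector describes
#' geometry-invariant attributes and passes through unchanged, staying
#' paired with the transformed image.
#'
#' @param sample a [LesionSample-class].
#' @return the transformed [LesionSample-class]. Consumes the current RNG
#'   stream (seed via the caller, e.g. [trainModel()]).
#' @export
augmentPair <- function(sample) {
  op <- sample(c("identity", "hflip", "vflip", "rot90", "rot180", "rot270",
                 "scale"), 1L)
  f <- if (op == "scale") stats::runif(1, 0.9, 1.1) else 1
  img <- sample@image
  out <- array(0, dim(img))
  for (c in 1:3)
    out[, , c] <- applyGeom(img[, , c], op, f, bilinear = TRUE,
                            fill = mean(img[, , c]))
  mask <- applyGeom(sample@mask, op, f, bilinear = FALSE, fill = 0)
  lesionSample(sample@id, clip01(out), mask, sample@metadata)
}

adamInit <- function(weights) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else array(0, dim(x) %||% length(x))
  }
  list(m = lapply(weights, zero), v = lapply(weights, zero), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  for (nm in names(grads)) {
    if (is.list(weights[[nm]])) {
      for (part in names(weights[[nm]])) {
        r <- upd(weights[[nm]][[part]], grads[[nm]][[part]],
                 state$m[[nm]][[part]], state$v[[nm]][[part]])
        weights[[nm]][[part]] <- r$w
        state$m[[nm]][[part]] <- r$m
        state$v[[nm]][[part]] <- r$v
      }
    } else {
      r <- upd(weights[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
      weights[[nm]] <- r$w
      state$m[[nm]] <- r$m
      state$v[[nm]] <- r$v
    }
  }
  list(weights = weights, state = state)
}

evalLossIoU <- function(model, samples, loss, batchSize) {
  tot <- 0; ious <- numeric(length(samples)); k <- 0L
  for (start in seq(1L, length(samples), by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, length(samples))
    bt <- samplesToBatch(samples[sel])
    fw <- nnForward(model, bt$x, bt$meta, stochastic = FALSE)
    lg <- lossAndGrad(fw$probs, bt$y, loss)
    tot <- tot + lg$loss * length(sel)
    for (j in seq_along(sel)) {
      k <- k + 1L
      ious[k] <- iouMetric(fw$probs[, , 1L, j], bt$y[, , 1L, j])
    }
  }
  list(loss = tot / length(samples), iou = mean(ious))
}

#' Train a model with Adam, validation checkpointing and early stopping
#'
#' After every epoch the validation loss is computed; the best-so-far
#' weights are checkpointed and training stops once
#' `cfg@earlyStopPatience` epochs pass without improvement (or at
#' `cfg@maxEpochs`). Fully seeded: two runs with the same seed, data and
#' configuration produce identical histories and weights.
#'
#' @param model a [MetaUNet-class] (weights are the starting point).
#' @param trainSamples,valSamples lists of [LesionSample-class].
#' @param cfg a [TrainConfig-class].
#' @return list with elements `model` (the checkpointed best model) and
#'   `history` (data.frame: epoch, trainLoss, valLoss, valIoU).
#' @export
trainModel <- function(model, trainSamples, valSamples, cfg = trainConfig()) {
  validObject(cfg)
  if (length(trainSamples) == 0L || length(valSamples) == 0L)
    stop("need non-empty training and validation sets")
  weights <- model@weights
  state <- adamInit(weights)
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  hist <- list()
  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@maxEpochs)) {
      ord <- sample(length(trainSamples))
      epochLoss <- 0
      for (start in seq(1L, length(ord), by = cfg@batchSize)) {
        sel <- ord[start:min(start + cfg@batchSize - 1L, length(ord))]
        batch <- trainSamples[sel]
        if (cfg@augment) batch <- lapply(batch, augmentPair)
        bt <- samplesToBatch(batch)
        model@weights <- weights
        fw <- nnForward(model, bt$x, bt$meta, stochastic = TRUE,
                        keepCache = TRUE)
        lg <- lossAndGrad(fw$probs, bt$y, cfg@loss)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        grads <- nnBackward(model, fw$cache, lg$dZ)
        st <- adamStep(weights, grads, state, cfg@learningRate)
        weights <- st$weights
        state <- st$state
        epochLoss <- epochLoss + lg$loss * length(sel)
      }
      model@weights <- weights
      ev <- evalLossIoU(model, valSamples, cfg@loss, cfg@batchSize)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainLoss = epochLoss / length(ord),
                                  valLoss = ev$loss, valIoU = ev$iou)
      if (ev$loss < best$loss)
        best <- list(loss = ev$loss, weights = weights, epoch = epoch)
      if (epoch - best$epoch > cfg@earlyStopPatience) break
    }
  })
  model@weights <- best$weights
  list(model = model, history = do.call(rbind, hist))
}
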