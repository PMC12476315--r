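# Forward and backward passes of the (metadata-fused) U-Net.
#
# Activations are arrays [H, W, C, N]. The forward pass optionally keeps
# per-layer caches (inputs, ReLU masks, pooling argmaxes, dropout masks) so
# the backward pass can run without recomputation; prediction paths drop
# the caches to keep memory flat.

reluA <- function(a) { a[a < 0] <- 0; a }

sigmoidA <- function(z) 1 / (1 + exp(-z))

concatCh <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Inverted dropout mask: zero with probability `rate`, survivors scaled by
# 1/(1-rate) so expectations match the deterministic network.
dropoutMask <- function(dims, rate) {
  array((stats::runif(prod(dims)) >= rate) / (1 - rate), dims)
}

# Stack samples into batch tensors (and metadata matrix).
samplesToBatch <- function(samples) {
  d <- dim(samples[[1]]@image)
  N <- length(samples)
  x <- array(0, c(d[1], d[2], 3L, N))
  y <- array(0, c(d[1], d[2], 1L, N))
  meta <- matrix(0, N, length(samples[[1]]@metadata))
  for (n in seq_len(N)) {
    x[, , , n] <- samples[[n]]@image
    y[, , 1L, n] <- samples[[n]]@mask
    meta[n, ] <- samples[[n]]@metadata
  }
  list(x = x, y = y, meta = meta,
       ids = vapply(samples, function(s) s@id, character(1)))
}

# Full forward pass. `stochastic` activates dropout sampling (training or
# Monte Carlo Dropout inference); dropout is a no-op unless the model was
# built with bayesian = TRUE and a positive rate.
nnForward <- function(model, x, meta = NULL, stochastic = FALSE,
                      keepCache = FALSE) {
  cfg <- model@config
  wts <- model@weights
  B <- length(cfg@encoderWidths)
  rate <- if (cfg@bayesian && stochastic) cfg@dropoutRate else 0
  if (usesMetadata(cfg) && is.null(meta))
    stop("this fusion strategy requires a metadata matrix")
  N <- dim(x)[4]
  cache <- if (keepCache) list(enc = vector("list", B),
                               dec = vector("list", B)) else NULL

  a <- x
  skips <- vector("list", B)
  for (i in seq_len(B)) {
    w1 <- wts[[sprintf("enc%d.conv1", i)]]
    w2 <- wts[[sprintf("enc%d.conv2", i)]]
    xin <- a
    a1 <- reluA(cpp_conv2d_fw(xin, w1$W, w1$b, 3L))
    a2 <- reluA(cpp_conv2d_fw(a1, w2$W, w2$b, 3L))
    m <- NULL
    if (rate > 0) { m <- dropoutMask(dim(a2), rate); a2 <- a2 * m }
    skips[[i]] <- a2
    pl <- cpp_maxpool2_fw(a2)
    if (keepCache) cache$enc[[i]] <- list(xin = xin, a1 = a1, a2 = a2,
                                          idx = pl$idx, mask = m)
    a <- pl$y
  }
  if (hasExtraPool(cfg)) {
    pl <- cpp_maxpool2_fw(a)
    if (keepCache) cache$extraIdx <- pl$idx
    a <- pl$y
  }
  wb1 <- wts[["bott.conv1"]]; wb2 <- wts[["bott.conv2"]]
  bIn <- a
  b1 <- reluA(cpp_conv2d_fw(bIn, wb1$W, wb1$b, 3L))
  b2 <- reluA(cpp_conv2d_fw(b1, wb2$W, wb2$b, 3L))
  bMask <- NULL
  if (rate > 0) { bMask <- dropoutMask(dim(b2), rate); b2 <- b2 * bMask }
  if (keepCache) cache$bott <- list(xin = bIn, a1 = b1, a2 = b2, mask = bMask)

  # Metadata branch.
  mEmb <- NULL
  if (usesMetadata(cfg)) {
    s <- bottleneckSize(cfg)
    if (usesEmbeddings(cfg)) {
      idxM <- metadataToIndices(meta, model@schema)
      U <- ncol(idxM)
      E <- matrix(0, N, U * cfg@embedDim)
      for (u in seq_len(U))
        E[, (u - 1L) * cfg@embedDim + seq_len(cfg@embedDim)] <-
          wts[[paste0("embed.", colnames(idxM)[u])]][idxM[, u], , drop = FALSE]
    } else {
      idxM <- NULL
      E <- meta
    }
    d1 <- wts[["meta.dense1"]]; d2 <- wts[["meta.dense2"]]
    h1 <- reluA(sweep(E %*% d1$W, 2L, d1$b, "+"))
    h2 <- reluA(sweep(h1 %*% d2$W, 2L, d2$b, "+"))
    mEmb <- array(0, c(s, s, 1L, N))
    for (n in seq_len(N)) mEmb[, , 1L, n] <- matrix(h2[n, ], s, s)
    if (keepCache) cache$meta <- list(E = E, h1 = h1, h2 = h2, idxM = idxM)
  }
  fused <- fuse(b2, mEmb, cfg@fusionStrategy, cfg@fusionWeights)

  # Decoder.
  a <- fused
  for (i in rev(seq_len(B))) {
    up <- wts[[sprintf("dec%d.up", i)]]
    w1 <- wts[[sprintf("dec%d.conv1", i)]]
    w2 <- wts[[sprintf("dec%d.conv2", i)]]
    xUp <- a
    z <- cpp_upconv2_fw(xUp, up$W, up$b)
    if (i == B && hasExtraPool(cfg)) z <- cpp_upsample2_fw(z)
    catd <- concatCh(skips[[i]], z)
    a1 <- reluA(cpp_conv2d_fw(catd, w1$W, w1$b, 3L))
    a2 <- reluA(cpp_conv2d_fw(a1, w2$W, w2$b, 3L))
    m <- NULL
    if (rate > 0) { m <- dropoutMask(dim(a2), rate); a2 <- a2 * m }
    if (keepCache) cache$dec[[i]] <- list(xUp = xUp, catd = catd, a1 = a1,
                                          a2 = a2, mask = m)
    a <- a2
  }
  wo <- wts[["out"]]
  zOut <- cpp_conv2d_fw(a, wo$W, wo$b, 1L)
  probs <- sigmoidA(zOut)
  if (keepCache) cache$outIn <- a
  list(probs = probs, cache = cache)
}

# Backward pass given dL/dz at the pre-sigmoid output. Returns gradients in
# the same named-list structure as the weights.
nnBackward <- function(model, cache, dZ) {
  cfg <- model@config
  wts <- model@weights
  B <- length(cfg@encoderWidths)
  g <- list()

  bw <- cpp_conv2d_bw(cache$outIn, wts[["out"]]$W, dZ, 1L)
  g[["out"]] <- list(W = bw$dW, b = bw$db)
  dA <- bw$dx

  dSkip <- vector("list", B)
  for (i in seq_len(B)) {  # reverse of execution order (stage 1 ran last)
    dc <- cache$dec[[i]]
    if (!is.null(dc$mask)) dA <- dA * dc$mask
    dA <- dA * (dc$a2 > 0)
    bw2 <- cpp_conv2d_bw(dc$a1, wts[[sprintf("dec%d.conv2", i)]]$W, dA, 3L)
    g[[sprintf("dec%d.conv2", i)]] <- list(W = bw2$dW, b = bw2$db)
    dA <- bw2$dx * (dc$a1 > 0)
    bw1 <- cpp_conv2d_bw(dc$catd, wts[[sprintf("dec%d.conv1", i)]]$W, dA, 3L)
    g[[sprintf("dec%d.conv1", i)]] <- list(W = bw1$dW, b = bw1$db)
    w <- cfg@encoderWidths[i]
    dSkip[[i]] <- bw1$dx[, , seq_len(w), , drop = FALSE]
    dUp <- bw1$dx[, , w + seq_len(w), , drop = FALSE]
    if (i == B && hasExtraPool(cfg)) dUp <- cpp_upsample2_bw(dUp)
    bwu <- cpp_upconv2_bw(dc$xUp, wts[[sprintf("dec%d.up", i)]]$W, dUp)
    g[[sprintf("dec%d.up", i)]] <- list(W = bwu$dW, b = bwu$db)
    dA <- bwu$dx
  }

  # Fusion backward: split dA into the image-feature and metadata parts.
  Cb <- cfg@bottleneckWidth
  dM <- NULL
  if (cfg@fusionStrategy %in% c("embedding_concat", "onehot_dense")) {
    dM <- dA[, , Cb + 1L, , drop = FALSE]
    dA <- dA[, , seq_len(Cb), , drop = FALSE]
  } else if (cfg@fusionStrategy == "weighted") {
    dM <- cfg@fusionWeights[2] *
      array(apply(dA, c(1, 2, 4), sum), c(dim(dA)[1], dim(dA)[2], 1L, dim(dA)[4]))
    dA <- cfg@fusionWeights[1] * dA
  }

  if (!is.null(dM)) {
    mc <- cache$meta
    s <- bottleneckSize(cfg)
    N <- dim(dM)[4]
    dH2 <- matrix(0, N, s * s)
    for (n in seq_len(N)) dH2[n, ] <- as.vector(dM[, , 1L, n])
    dH2 <- dH2 * (mc$h2 > 0)
    d2 <- wts[["meta.dense2"]]; d1 <- wts[["meta.dense1"]]
    g[["meta.dense2"]] <- list(W = t(mc$h1) %*% dH2, b = colSums(dH2))
    dH1 <- (dH2 %*% t(d2$W)) * (mc$h1 > 0)
    g[["meta.dense1"]] <- list(W = t(mc$E) %*% dH1, b = colSums(dH1))
    if (usesEmbeddings(cfg)) {
      dE <- dH1 %*% t(d1$W)
      idxM <- mc$idxM
      for (u in seq_len(ncol(idxM))) {
        nm <- paste0("embed.", colnames(idxM)[u])
        gE <- matrix(0, nrow(wts[[nm]]), ncol(wts[[nm]]))
        cols <- (u - 1L) * cfg@embedDim + seq_len(cfg@embedDim)
        for (n in seq_len(nrow(idxM)))
          gE[idxM[n, u], ] <- gE[idxM[n, u], ] + dE[n, cols]
        g[[nm]] <- gE
      }
    }
  }

  bc <- cache$bott
  if (!is.null(bc$mask)) dA <- dA * bc$mask
  dA <- dA * (bc$a2 > 0)
  bw2 <- cpp_conv2d_bw(bc$a1, wts[["bott.conv2"]]$W, dA, 3L)
  g[["bott.conv2"]] <- list(W = bw2$dW, b = bw2$db)
  dA <- bw2$dx * (bc$a1 > 0)
  bw1 <- cpp_conv2d_bw(bc$xin, wts[["bott.conv1"]]$W, dA, 3L)
  g[["bott.conv1"]] <- list(W = bw1$dW, b = bw1$db)
  dA <- bw1$dx
  if (hasExtraPool(cfg)) dA <- cpp_maxpool2_bw(dA, cache$extraIdx)

  for (i in rev(seq_len(B))) {
    ec <- cache$enc[[i]]
    dA <- cpp_maxpool2_bw(dA, ec$idx) + dSkip[[i]]
    if (!is.null(ec$mask)) dA <- dA * ec$mask
    dA <- dA * (ec$a2 > 0)
    bw2 <- cpp_conv2d_bw(ec$a1, wts[[sprintf("enc%d.conv2", i)]]$W, dA, 3L)
    g[[sprintf("enc%d.conv2", i)]] <- list(W = bw2$dW, b = bw2$db)
    dA <- bw2$dx * (ec$a1 > 0)
    bw1 <- cpp_conv2d_bw(ec$xin, wts[[sprintf("enc%d.conv1", i)]]$W, dA, 3L)
    g[[sprintf("enc%d.conv1", i)]] <- list(W = bw1$dW, b = bw1$db)
    dA <- bw1$dx
  }
  g
}

#' Segment samples with a built model
#'
#' Deterministic forward pass (dropout off). For Monte Carlo Dropout
#' ensembles use [mcdPredict()].
#'
#' @param model a [MetaUNet-class].
#' @param samples a [LesionSample-class] or list of them.
#' @param batchSize forward-pass batch size.
#' @return a named list of H x W lesion-probability matrices.
#' @export
predictModel <- function(model, samples, batchSize = 8L) {
  if (is(samples, "LesionSample")) samples <- list(samples)
  out <- vector("list", length(samples))
  for (start in seq(1L, length(samples), by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, length(samples))
    bt <- samplesToBatch(samples[sel])
    fw <- nnForward(model, bt$x, bt$meta, stochastic = FALSE)
    for (j in seq_along(sel)) out[[sel[j]]] <- fw$probs[, , 1L, j]
  }
  names(out) <- vapply(samples, function(s) s@id, character(1))
  out
}
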