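#' Configure the (metadata-fused) U-Net architecture
#'
#' Defaults pin the reference configuration: 224 x 224 x 3 input, encoder
#' widths 64-128-256-512 (two 3 x 3 same-padded convolutions + ReLU per
#' block, each followed by 2 x 2 max pooling), a fifth width-preserving
#' pool bringing 14 x 14 down to 7 x 7, a 1024-channel bottleneck, a
#' metadata branch (per-group embeddings, dense 36 then dense `s^2` with
#' ReLU, reshaped to `s x s x 1` where `s` is the bottleneck size, 49 = 7^2
#' for the default), embedding-concat fusion, and a mirrored decoder
#' (2 x 2 transposed convolutions, skip concatenation, two 3 x 3
#' convolutions, final 1 x 1 convolution + sigmoid).
#'
#' @param inputSize,inputChannels,encoderWidths,bottleneckWidth,nPool,metadataWidth,embedDim,fusionStrategy,fusionWeights,dropoutRate,bayesian,outChannels
#'   see [ModelConfig-class].
#' @return a validated [ModelConfig-class].
#' @export
modelConfig <- function(inputSize = 224L, inputChannels = 3L,
                        encoderWidths = c(64L, 128L, 256L, 512L),
                        bottleneckWidth = 1024L, nPool = 5L,
                        metadataWidth = 29L, embedDim = 4L,
                        fusionStrategy = "embedding_concat",
                        fusionWeights = c(0.7, 0.3), dropoutRate = 0.5,
                        bayesian = FALSE, outChannels = 1L) {
  new("ModelConfig", inputSize = as.integer(inputSize),
      inputChannels = as.integer(inputChannels),
      encoderWidths = as.integer(encoderWidths),
      bottleneckWidth = as.integer(bottleneckWidth), nPool = as.integer(nPool),
      metadataWidth = as.integer(metadataWidth), embedDim = as.integer(embedDim),
      fusionStrategy = fusionStrategy, fusionWeights = fusionWeights,
      dropoutRate = dropoutRate, bayesian = bayesian,
      outChannels = as.integer(outChannels))
}

# Bottleneck spatial size: input halved once per pool.
bottleneckSize <- function(cfg) cfg@inputSize %/% (2L^cfg@nPool)

hasExtraPool <- function(cfg) cfg@nPool == length(cfg@encoderWidths) + 1L

usesMetadata <- function(cfg) cfg@fusionStrategy != "none"

usesEmbeddings <- function(cfg)
  cfg@fusionStrategy %in% c("embedding_concat", "weighted")

# Channel count entering the decoder.
fusedChannels <- function(cfg) {
  cfg@bottleneckWidth +
    if (cfg@fusionStrategy %in% c("embedding_concat", "onehot_dense")) 1L else 0L
}

layerRow <- function(component, name, kind, input, output, params) {
  data.frame(component = component, name = name, kind = kind,
             input = input, output = output, params = as.numeric(params),
             stringsAsFactors = FALSE)
}

convParams <- function(k, cin, cout) (k * k * cin + 1) * cout
denseParams <- function(nin, nout) (nin + 1) * nout

shp <- function(s, c) sprintf("%dx%dx%d", s, s, c)

#' Layer plan of the encoder and bottleneck
#'
#' @param cfg a [ModelConfig-class].
#' @return a data.frame of layer records (one row per layer; pooling and
#'   activation layers carry zero parameters).
#' @export
buildEncoder <- function(cfg) {
  validObject(cfg)
  rows <- list()
  s <- cfg@inputSize
  cin <- cfg@inputChannels
  for (i in seq_along(cfg@encoderWidths)) {
    w <- cfg@encoderWidths[i]
    rows[[length(rows) + 1]] <- layerRow("encoder", sprintf("enc%d.conv1", i),
      "conv3x3+relu", shp(s, cin), shp(s, w), convParams(3, cin, w))
    rows[[length(rows) + 1]] <- layerRow("encoder", sprintf("enc%d.conv2", i),
      "conv3x3+relu", shp(s, w), shp(s, w), convParams(3, w, w))
    rows[[length(rows) + 1]] <- layerRow("encoder", sprintf("enc%d.pool", i),
      "maxpool2x2", shp(s, w), shp(s %/% 2, w), 0)
    s <- s %/% 2
    cin <- w
  }
  if (hasExtraPool(cfg)) {
    rows[[length(rows) + 1]] <- layerRow("encoder", "enc.extra_pool",
      "maxpool2x2", shp(s, cin), shp(s %/% 2, cin), 0)
    s <- s %/% 2
  }
  wb <- cfg@bottleneckWidth
  rows[[length(rows) + 1]] <- layerRow("encoder", "bott.conv1", "conv3x3+relu",
    shp(s, cin), shp(s, wb), convParams(3, cin, wb))
  rows[[length(rows) + 1]] <- layerRow("encoder", "bott.conv2", "conv3x3+relu",
    shp(s, wb), shp(s, wb), convParams(3, wb, wb))
  do.call(rbind, rows)
}

#' Layer plan of the metadata branch
#'
#' For embedding-based fusion each attribute group is embedded (one table
#' per one-hot group, one 2-row table per binary flag), embeddings are
#' concatenated and passed through dense(36, ReLU) and dense(`s^2`, ReLU),
#' then reshaped to `s x s x 1` (`s` = bottleneck size; the second dense
#' has 49 units for the reference 7 x 7 bottleneck). One-hot+dense fusion
#' skips the embeddings and feeds the raw metadata vector to the same pair
#' of dense layers.
#'
#' @param cfg a [ModelConfig-class].
#' @param schema a [MetadataSchema-class]; its width must equal
#'   `cfg@metadataWidth`.
#' @return a data.frame of layer records (empty for `fusionStrategy
#'   = "none"`).
#' @export
buildMetadataBranch <- function(cfg, schema = defaultMetadataSchema()) {
  validObject(cfg)
  if (!usesMetadata(cfg))
    return(data.frame(component = character(0), name = character(0),
                      kind = character(0), input = character(0),
                      output = character(0), params = numeric(0)))
  if (schemaWidth(schema) != cfg@metadataWidth)
    stop(sprintf("schema width %d does not match cfg metadataWidth %d",
                 schemaWidth(schema), cfg@metadataWidth))
  s <- bottleneckSize(cfg)
  rows <- list()
  if (usesEmbeddings(cfg)) {
    units <- schemaEmbedUnits(schema)
    for (nm in names(units))
      rows[[length(rows) + 1]] <- layerRow("metadata", paste0("embed.", nm),
        "embedding", sprintf("%d", units[[nm]]$vocab),
        sprintf("%d", cfg@embedDim), units[[nm]]$vocab * cfg@embedDim)
    din <- length(units) * cfg@embedDim
  } else {
    din <- cfg@metadataWidth
  }
  rows[[length(rows) + 1]] <- layerRow("metadata", "meta.dense1", "dense+relu",
    sprintf("%d", din), "36", denseParams(din, 36))
  rows[[length(rows) + 1]] <- layerRow("metadata", "meta.dense2", "dense+relu",
    "36", sprintf("%d", s * s), denseParams(36, s * s))
  rows[[length(rows) + 1]] <- layerRow("metadata", "meta.reshape", "reshape",
    sprintf("%d", s * s), shp(s, 1), 0)
  do.call(rbind, rows)
}

#' Layer plan of the decoder
#'
#' Mirrors the encoder: per stage a 2 x 2 stride-2 transposed convolution
#' halving the channel count, concatenation with the same-resolution
#' encoder skip (a no-op crop, since all convolutions are zero-padded),
#' and two 3 x 3 convolutions with ReLU. With the extra fifth pool the
#' first stage inserts a parameter-free nearest-neighbour 2x upsample so
#' skip resolutions line up. A final 1 x 1 convolution + sigmoid produces
#' the lesion-probability map at the input resolution.
#'
#' @param cfg a [ModelConfig-class].
#' @return a data.frame of layer records.
#' @export
buildDecoder <- function(cfg) {
  validObject(cfg)
  rows <- list()
  B <- length(cfg@encoderWidths)
  s <- bottleneckSize(cfg)
  cin <- fusedChannels(cfg)
  for (i in rev(seq_len(B))) {
    w <- cfg@encoderWidths[i]
    rows[[length(rows) + 1]] <- layerRow("decoder", sprintf("dec%d.up", i),
      "upconv2x2", shp(s, cin), shp(2 * s, w), (4 * cin + 1) * w)
    s <- 2 * s
    if (i == B && hasExtraPool(cfg)) {
      rows[[length(rows) + 1]] <- layerRow("decoder", sprintf("dec%d.upsample", i),
        "nn_upsample2x", shp(s, w), shp(2 * s, w), 0)
      s <- 2 * s
    }
    rows[[length(rows) + 1]] <- layerRow("decoder", sprintf("dec%d.concat", i),
      "crop_and_copy", shp(s, w), shp(s, 2 * w), 0)
    rows[[length(rows) + 1]] <- layerRow("decoder", sprintf("dec%d.conv1", i),
      "conv3x3+relu", shp(s, 2 * w), shp(s, w), convParams(3, 2 * w, w))
    rows[[length(rows) + 1]] <- layerRow("decoder", sprintf("dec%d.conv2", i),
      "conv3x3+relu", shp(s, w), shp(s, w), convParams(3, w, w))
    cin <- w
  }
  rows[[length(rows) + 1]] <- layerRow("decoder", "out", "conv1x1+sigmoid",
    shp(s, cin), shp(s, cfg@outChannels), convParams(1, cin, cfg@outChannels))
  do.call(rbind, rows)
}

#' Count trainable parameters of a layer plan
#'
#' Convolutions and transposed convolutions contribute
#' `(k_h * k_w * C_in + 1) * C_out`, dense layers `(n_in + 1) * n_out`,
#' embeddings `vocabulary * dim`; pooling, upsampling, concatenation and
#' activations are parameter-free.
#'
#' @param description a layer-plan data.frame (from [buildEncoder()],
#'   [buildDecoder()], [buildMetadataBranch()] or a [MetaUNet-class]
#'   `@description`).
#' @return integer-valued total parameter count.
#' @examples
#' countParameters(buildEncoder(modelConfig()))  # 18843200
#' @export
countParameters <- function(description) {
  if (nrow(description) == 0L) return(0)
  sum(description$params)
}

#' Build the full network: layer plan plus initialized weights
#'
#' Composes encoder, metadata branch (unless `fusionStrategy = "none"`),
#' fusion and decoder. Weights use He-uniform initialization for
#' convolutional and dense layers and uniform(-0.05, 0.05) for embedding
#' tables; biases start at zero. With `bayesian = TRUE`, dropout (rate
#' `cfg@dropoutRate`) is applied after each two-convolution block during
#' training and Monte Carlo Dropout inference; dropout carries no
#' parameters, so the count is unchanged.
#'
#' @param cfg a [ModelConfig-class].
#' @param schema a [MetadataSchema-class].
#' @param seed integer seed for the weight initialization.
#' @return a [MetaUNet-class].
#' @export
buildModel <- function(cfg, schema = defaultMetadataSchema(), seed = 1L) {
  validObject(cfg)
  desc <- rbind(buildEncoder(cfg), buildMetadataBranch(cfg, schema),
                buildDecoder(cfg))
  weights <- withSeed(seed, initWeights(cfg, schema))
  new("MetaUNet", config = cfg, schema = schema, description = desc,
      weights = weights)
}

heConv <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))
  list(W = matrix(stats::runif(k * k * cin * cout, -lim, lim), k * k * cin, cout),
       b = numeric(cout))
}

heUp <- function(cin, cout) {
  lim <- sqrt(6 / (4 * cin))
  list(W = matrix(stats::runif(cin * 4 * cout, -lim, lim), cin, 4 * cout),
       b = numeric(cout))
}

heDense <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  list(W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
       b = numeric(nout))
}

initWeights <- function(cfg, schema) {
  w <- list()
  cin <- cfg@inputChannels
  for (i in seq_along(cfg@encoderWidths)) {
    wd <- cfg@encoderWidths[i]
    w[[sprintf("enc%d.conv1", i)]] <- heConv(3, cin, wd)
    w[[sprintf("enc%d.conv2", i)]] <- heConv(3, wd, wd)
    cin <- wd
  }
  w[["bott.conv1"]] <- heConv(3, cin, cfg@bottleneckWidth)
  w[["bott.conv2"]] <- heConv(3, cfg@bottleneckWidth, cfg@bottleneckWidth)
  if (usesMetadata(cfg)) {
    s <- bottleneckSize(cfg)
    if (usesEmbeddings(cfg)) {
      units <- schemaEmbedUnits(schema)
      for (nm in names(units))
        w[[paste0("embed.", nm)]] <-
          matrix(stats::runif(units[[nm]]$vocab * cfg@embedDim, -0.05, 0.05),
                 units[[nm]]$vocab, cfg@embedDim)
      din <- length(units) * cfg@embedDim
    } else {
      din <- cfg@metadataWidth
    }
    w[["meta.dense1"]] <- heDense(din, 36)
    w[["meta.dense2"]] <- heDense(36, s * s)
  }
  B <- length(cfg@encoderWidths)
  cin <- fusedChannels(cfg)
  for (i in rev(seq_len(B))) {
    wd <- cfg@encoderWidths[i]
    w[[sprintf("dec%d.up", i)]] <- heUp(cin, wd)
    w[[sprintf("dec%d.conv1", i)]] <- heConv(3, 2 * wd, wd)
    w[[sprintf("dec%d.conv2", i)]] <- heConv(3, wd, wd)
    cin <- wd
  }
  w[["out"]] <- heConv(1, cin, cfg@outChannels)
  w
}

#' Fuse bottleneck image features with the processed metadata map
#'
#' @param fLatent numeric `s x s x C x N` bottleneck feature array.
#' @param mEmbed numeric `s x s x 1 x N` metadata map (ignored for
#'   `strategy = "none"`).
#' @param strategy one of `"none"`, `"onehot_dense"`, `"weighted"`,
#'   `"embedding_concat"`. Both concat strategies append the metadata map
#'   as an extra channel; `"weighted"` forms `w_img * fLatent + w_meta *
#'   mEmbed` with the map broadcast across channels.
#' @param weights numeric `(w_img, w_meta)`, used by `"weighted"`; must sum
#'   to 1.
#' @return the fused feature array.
#' @export
fuse <- function(fLatent, mEmbed, strategy, weights = c(0.7, 0.3)) {
  d <- dim(fLatent)
  switch(strategy,
    none = fLatent,
    embedding_concat = ,
    onehot_dense = {
      stopifnot(all(dim(mEmbed)[c(1, 2, 4)] == d[c(1, 2, 4)]))
      out <- array(0, c(d[1], d[2], d[3] + 1L, d[4]))
      out[, , seq_len(d[3]), ] <- fLatent
      out[, , d[3] + 1L, ] <- mEmbed
      out
    },
    weighted = {
      if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
        stop("weighted fusion weights must be non-negative and sum to 1")
      bcast <- array(mEmbed[, , rep(1L, d[3]), , drop = FALSE], d)
      weights[1] * fLatent + weights[2] * bcast
    },
    stop("unknown fusion strategy: ", strategy))
}

#' @describeIn MetaUNet-class architecture summary with parameter counts
#' @param object a `MetaUNet`.
#' @export
setMethod("show", "MetaUNet", function(object) {
  cfg <- object@config
  total <- countParameters(object@description)
  cat(sprintf("MetaUNet: %dx%dx%d input, bottleneck %dx%dx%d, fusion '%s'%s\n",
              cfg@inputSize, cfg@inputSize, cfg@inputChannels,
              bottleneckSize(cfg), bottleneckSize(cfg), cfg@bottleneckWidth,
              cfg@fusionStrategy,
              if (cfg@bayesian) sprintf(", MC dropout %.2f", cfg@dropoutRate) else ""))
  bycomp <- tapply(object@description$params, object@description$component, sum)
  for (nm in names(bycomp))
    cat(sprintf("  %-9s %12s parameters\n", nm, format(bycomp[[nm]], big.mark = ",")))
  cat(sprintf("  total     %12s parameters (%.1f M)\n",
              format(total, big.mark = ","), total / 1e6))
  invisible(NULL)
})

#' Dump a layer plan as CSV for the parameter-count audit
#'
#' @param description a layer-plan data.frame.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
writeLayerTable <- function(description, path) {
  utils::write.csv(description, path, row.names = FALSE)
  invisible(path)
}
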