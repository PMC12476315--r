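#' @useDynLib LesionSegUQ, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats runif rnorm rbinom median quantile sd setNames
#' @importFrom utils read.csv write.csv head packageVersion
NULL

#' Metadata schema: named attribute groups over the 29 metadata columns
#'
#' A `MetadataSchema` describes how the flat metadata vector decomposes into
#' attribute groups. One-hot groups (e.g. diagnosis) occupy one column per
#' category and must have exactly one active category; binary groups (e.g.
#' the six colour flags) occupy one independent 0/1 column per flag.
#'
#' @slot groups list of group descriptors, each a list with elements
#'   `name` (character), `type` (`"onehot"` or `"binary"`) and
#'   `categories` (character vector of category / flag labels).
#' @seealso [defaultMetadataSchema()], [schemaWidth()], [readSchema()]
#' @export
setClass("MetadataSchema", representation(groups = "list"))

setValidity("MetadataSchema", function(object) {
  g <- object@groups
  if (length(g) == 0L) return("schema has no groups")
  nm <- vapply(g, function(x) x$name, character(1))
  if (anyDuplicated(nm)) return("group names must be unique")
  for (x in g) {
    if (!x$type %in% c("onehot", "binary"))
      return(sprintf("group '%s': type must be 'onehot' or 'binary'", x$name))
    if (length(x$categories) < 1L)
      return(sprintf("group '%s': needs at least one category", x$name))
    if (x$type == "onehot" && length(x$categories) < 2L)
      return(sprintf("group '%s': one-hot group needs >= 2 categories", x$name))
  }
  TRUE
})

#' A single lesion sample: image, mask, metadata vector and identifier
#'
#' @slot id character identifier.
#' @slot image numeric H x W x 3 array with values in `[0, 1]`.
#' @slot mask numeric H x W matrix with values in `{0, 1}`.
#' @slot metadata numeric metadata vector (29 columns under the default
#'   schema); one-hot / binary layout is governed by a [MetadataSchema].
#' @seealso [readSample()], [generateSample()], [resizeSample()]
#' @export
setClass("LesionSample", representation(
  id = "character", image = "array", mask = "matrix", metadata = "numeric"))

setValidity("LesionSample", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) return("image must be H x W x 3")
  if (!all(d[1:2] == dim(object@mask)))
    return(sprintf("image (%dx%d) and mask (%dx%d) spatial dims differ",
                   d[1], d[2], nrow(object@mask), ncol(object@mask)))
  if (min(object@image) < -1e-9 || max(object@image) > 1 + 1e-9)
    return("image values must lie in [0, 1]")
  if (!all(object@mask %in% c(0, 1))) return("mask values must be 0/1")
  TRUE
})

#' Train/validation/test split of sample identifiers
#'
#' @slot train,val,test character vectors of sample ids (pairwise disjoint).
#' @slot seed integer seed used to shuffle before partitioning.
#' @seealso [splitDataset()]
#' @export
setClass("DatasetSplit", representation(
  train = "character", val = "character", test = "character", seed = "integer"))

setValidity("DatasetSplit", function(object) {
  all_ids <- c(object@train, object@val, object@test)
  if (anyDuplicated(all_ids)) return("split partitions are not disjoint")
  TRUE
})

#' Configuration of the synthetic dermoscopy generator
#'
#' Defaults emulate moderately easy dermoscopic images: a deformed-ellipse
#' lesion darker than a textured skin background, light noise and a small
#' boundary blur. [makeAmbiguousTask()] derives a hard variant.
#'
#' @slot imageSize integer edge length in pixels.
#' @slot nSamples integer number of samples in a dataset.
#' @slot lesionFracRange numeric length-2, lesion diameter as a fraction of
#'   the image edge.
#' @slot sigmaB numeric boundary blur (Gaussian sd, pixels).
#' @slot contrast numeric lesion/background contrast in `(0, 1]`.
#' @slot prevalence named list: per one-hot group a probability vector over
#'   its categories, per binary group a per-flag Bernoulli probability.
#' @slot textureAmp named numeric amplitudes of the attribute overlays
#'   (intensity units).
#' @slot sigmaN numeric pixel noise sd.
#' @slot polarityByDiagnosis logical; if `TRUE` the lesion is darker than
#'   the background iff diagnosis = melanoma, lighter otherwise (the
#'   metadata-resolvable ambiguity used by [makeAmbiguousTask()]).
#' @slot seed integer master seed; per-sample streams are derived from it.
#' @seealso [generatorConfig()], [generateDataset()]
#' @export
setClass("GeneratorConfig", representation(
  imageSize = "integer", nSamples = "integer", lesionFracRange = "numeric",
  sigmaB = "numeric", contrast = "numeric", prevalence = "list",
  textureAmp = "numeric", sigmaN = "numeric", polarityByDiagnosis = "logical",
  seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (object@imageSize < 16L) return("imageSize must be >= 16")
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (length(object@lesionFracRange) != 2L ||
      any(object@lesionFracRange <= 0) || diff(object@lesionFracRange) < 0)
    return("lesionFracRange must be a non-empty positive range")
  if (object@contrast <= 0 || object@contrast > 1)
    return("contrast must lie in (0, 1]")
  if (object@sigmaB < 0 || object@sigmaN < 0)
    return("sigmaB and sigmaN must be >= 0")
  TRUE
})

#' Architecture configuration of the (metadata-fused) U-Net
#'
#' The reference configuration (all defaults) is the 224 x 224 network with
#' encoder widths 64-128-256-512, a 1024-channel bottleneck at 7 x 7 reached
#' through five pooling steps, a metadata branch embedding the 29 attributes
#' and projecting them through dense layers of 36 and 49 units to a 7 x 7 x 1
#' map, and embedding-concat fusion; it counts about 31 million trainable
#' parameters.
#'
#' @slot inputSize integer image edge length (must be divisible by
#'   `2^nPool`).
#' @slot inputChannels integer, 3 for RGB.
#' @slot encoderWidths integer vector of per-block channel widths.
#' @slot bottleneckWidth integer bottleneck channels.
#' @slot nPool integer number of 2x2 max-pools; either
#'   `length(encoderWidths)` (classic U-Net) or `length(encoderWidths) + 1`
#'   (an extra width-preserving pool before the bottleneck, mirrored by a
#'   parameter-free nearest-neighbour upsample in the decoder).
#' @slot metadataWidth integer width of the flat metadata vector.
#' @slot embedDim integer embedding dimension per attribute group.
#' @slot fusionStrategy one of `"none"`, `"onehot_dense"`, `"weighted"`,
#'   `"embedding_concat"`.
#' @slot fusionWeights numeric `(w_img, w_meta)` for `"weighted"`; must sum
#'   to 1.
#' @slot dropoutRate numeric in `[0, 1)`; used when `bayesian = TRUE`.
#' @slot bayesian logical; place dropout after each convolutional block.
#' @slot outChannels integer output channels (1: sigmoid lesion probability).
#' @seealso [modelConfig()], [buildModel()], [countParameters()]
#' @export
setClass("ModelConfig", representation(
  inputSize = "integer", inputChannels = "integer", encoderWidths = "integer",
  bottleneckWidth = "integer", nPool = "integer", metadataWidth = "integer",
  embedDim = "integer", fusionStrategy = "character", fusionWeights = "numeric",
  dropoutRate = "numeric", bayesian = "logical", outChannels = "integer"))

setValidity("ModelConfig", function(object) {
  B <- length(object@encoderWidths)
  if (!object@nPool %in% c(B, B + 1L))
    return("nPool must equal length(encoderWidths) or length(encoderWidths)+1")
  if (object@inputSize %% (2L^object@nPool) != 0L)
    return(sprintf("inputSize %d not divisible by 2^nPool = %d",
                   object@inputSize, 2L^object@nPool))
  if (!object@fusionStrategy %in%
      c("none", "onehot_dense", "weighted", "embedding_concat"))
    return("unknown fusionStrategy")
  if (object@fusionStrategy == "weighted") {
    w <- object@fusionWeights
    if (length(w) != 2L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      return("weighted fusion requires w_img + w_meta = 1, both >= 0")
  }
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  TRUE
})

#' Training hyper-parameters
#'
#' Defaults follow standard practice for this architecture: Adam at learning
#' rate 1e-4, batch size 16, at most 200 epochs with early stopping at
#' patience 20, checkpointing on minimum validation loss.
#'
#' @slot learningRate numeric Adam step size.
#' @slot batchSize integer.
#' @slot maxEpochs integer.
#' @slot earlyStopPatience integer epochs without validation-loss
#'   improvement before stopping.
#' @slot loss `"bce"` or `"iou"`.
#' @slot augment logical, paired geometric augmentation of image + mask.
#' @slot seed integer seed for shuffling, augmentation and dropout.
#' @seealso [trainConfig()], [trainModel()]
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric", batchSize = "integer", maxEpochs = "integer",
  earlyStopPatience = "integer", loss = "character", augment = "logical",
  seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  if (object@earlyStopPatience < 0L) return("earlyStopPatience must be >= 0")
  if (!object@loss %in% c("bce", "iou")) return("loss must be 'bce' or 'iou'")
  TRUE
})

#' A built (metadata-fused) U-Net: layer plan plus weights
#'
#' @slot config the [ModelConfig-class] the network was built from.
#' @slot schema the [MetadataSchema-class] governing the metadata branch.
#' @slot description data.frame layer table (component, name, kind, shapes,
#'   parameter count).
#' @slot weights named list of weight arrays.
#' @seealso [buildModel()], [predictModel()], [trainModel()]
#' @export
setClass("MetaUNet", representation(
  config = "ModelConfig", schema = "MetadataSchema",
  description = "data.frame", weights = "list"))

#' An ensemble of T stochastic segmentations of one image
#'
#' Holds the Monte Carlo Dropout forward passes as a `T x H x W x 2` array
#' of per-pixel class probabilities (class 1 = lesion, class 2 = background;
#' the sigmoid output p is materialized as the distribution (p, 1 - p)).
#'
#' @slot probs numeric `T x H x W x 2` array.
#' @slot id character id of the segmented sample.
#' @slot seed integer seed of the dropout draws.
#' @seealso [mcdPredict()], [uncertaintyReport()]
#' @export
setClass("PredictionEnsemble", representation(
  probs = "array", id = "character", seed = "integer"))

setValidity("PredictionEnsemble", function(object) {
  d <- dim(object@probs)
  if (length(d) != 4L || d[4] != 2L) return("probs must be T x H x W x 2")
  if (min(object@probs) < -1e-9 || max(object@probs) > 1 + 1e-9)
    return("probabilities must lie in [0, 1]")
  s <- object@probs[, , , 1L, drop = FALSE] + object@probs[, , , 2L, drop = FALSE]
  if (max(abs(s - 1)) > 1e-6) return("per-pixel class probabilities must sum to 1")
  TRUE
})

#' Per-image uncertainty maps, summary means and aggregate score
#'
#' @slot id character sample id.
#' @slot maps list of H x W matrices `C`, `H`, `MI`, `EPKL`.
#' @slot means named numeric per-image means of the four measures.
#' @slot normalized named numeric cohort min-max normalized means
#'   (`NA` until [normalizeMeasures()] has been applied).
#' @slot uTot numeric aggregate score (`NA` until normalized).
#' @slot weights numeric aggregation weights `(alpha, beta, gamma, delta)`.
#' @slot cohort character fingerprint of the normalization cohort.
#' @seealso [uncertaintyReport()], [normalizeMeasures()],
#'   [rankByUncertainty()]
#' @export
setClass("UncertaintyReport", representation(
  id = "character", maps = "list", means = "numeric", normalized = "numeric",
  uTot = "numeric", weights = "numeric", cohort = "character"))
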