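#' Configure the synthetic dermoscopy generator
#'
#' The generator draws a lesion as a deformed ellipse (low-frequency radial
#' harmonics), places it on a smoothly textured skin-like background, and
#' renders one local texture overlay per active metadata attribute: a
#' reticular grid (pigment network), dark dots (dots/globules), radial
#' spokes crossing the boundary (streaks), pale interior patches
#' (regression), a blue tint (blue-whitish veil) and small colour blotches
#' (colour flags). Asymmetry and border irregularity deform the lesion
#' outline itself. The mask is the exact region indicator before any edge
#' blurring, and the metadata one-hot encodes exactly the attributes
#' rendered.
#'
#' @param imageSize image edge length in pixels.
#' @param nSamples dataset size.
#' @param lesionFracRange lesion diameter range as a fraction of the edge.
#' @param sigmaB boundary blur sd in pixels (0 = hard edge).
#' @param contrast lesion/background contrast in `(0, 1]`.
#' @param prevalence named list of per-group category probabilities
#'   (one-hot groups) or per-flag probabilities (binary groups).
#' @param textureAmp named amplitudes of the attribute overlays.
#' @param sigmaN additive Gaussian pixel noise sd.
#' @param polarityByDiagnosis if `TRUE`, the lesion is darker than the
#'   background iff diagnosis = melanoma and lighter otherwise.
#' @param seed master seed; every sample derives its own independent
#'   streams from it, so sample `i` is reproducible regardless of order.
#' @return a [GeneratorConfig-class].
#' @seealso [generateSample()], [generateDataset()], [makeAmbiguousTask()]
#' @export
generatorConfig <- function(imageSize = 64L, nSamples = 50L,
                            lesionFracRange = c(0.35, 0.60),
                            sigmaB = 1.0, contrast = 0.45,
                            prevalence = defaultPrevalence(),
                            textureAmp = defaultTextureAmp(),
                            sigmaN = 0.02, polarityByDiagnosis = FALSE,
                            seed = 1L) {
  new("GeneratorConfig", imageSize = as.integer(imageSize),
      nSamples = as.integer(nSamples), lesionFracRange = lesionFracRange,
      sigmaB = sigmaB, contrast = contrast, prevalence = prevalence,
      textureAmp = textureAmp, sigmaN = sigmaN,
      polarityByDiagnosis = polarityByDiagnosis, seed = as.integer(seed))
}

#' @rdname generatorConfig
#' @export
defaultPrevalence <- function() {
  list(diagnosis = c(0.4, 0.3, 0.3), asymmetry = c(0.5, 0.3, 0.2),
       pigment_network = c(0.4, 0.3, 0.3), dots_globules = c(0.4, 0.3, 0.3),
       streaks = c(0.5, 0.25, 0.25), regression = c(0.6, 0.25, 0.15),
       blue_whitish_veil = c(0.7, 0.3), border_irregularity = c(0.5, 0.3, 0.2),
       colors = rep(0.3, 6))
}

#' @rdname generatorConfig
#' @export
defaultTextureAmp <- function() {
  c(pigment_network = 0.08, dots_globules = 0.14, streaks = 0.12,
    regression = 0.10, blue_whitish_veil = 0.08, colors = 0.05)
}

#' @describeIn GeneratorConfig-class compact printout
#' @param object a `GeneratorConfig`.
#' @export
setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0("GeneratorConfig: %d samples of %dx%d px, contrast %.2f, ",
                     "edge blur %.2f px, noise sd %.3f, seed %d%s\n"),
              object@nSamples, object@imageSize, object@imageSize,
              object@contrast, object@sigmaB, object@sigmaN, object@seed,
              if (object@polarityByDiagnosis) ", polarity tied to diagnosis" else ""))
  invisible(NULL)
})

# Per-sample base seed derived from the dataset seed and the sample index.
sampleSeedFor <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1048573 * 2039 + index * 7919) %% 2147483647)
}

# Draw one metadata vector according to the configured prevalences.
sampleMetadata <- function(cfg, schema) {
  idx <- schemaGroupIndex(schema)
  out <- numeric(schemaWidth(schema))
  for (g in schema@groups) {
    p <- cfg@prevalence[[g$name]]
    if (is.null(p)) p <- rep(1 / length(g$categories), length(g$categories))
    cols <- idx[[g$name]]
    if (g$type == "onehot") {
      k <- sample.int(length(cols), 1L, prob = p)
      out[cols[k]] <- 1
    } else {
      out[cols] <- stats::rbinom(length(cols), 1L, p)
    }
  }
  out
}

activeCategory <- function(metadata, schema, group) {
  idx <- schemaGroupIndex(schema)[[group]]
  g <- schema@groups[[which(vapply(schema@groups, function(x) x$name,
                                   character(1)) == group)]]
  g$categories[which(metadata[idx] == 1)]
}

# Lesion outline: radius as a function of angle with low-frequency
# harmonics, plus asymmetry (k = 1) and border-irregularity (high-k) terms.
lesionRegion <- function(S, frac, asymAmp, borderAmp) {
  cy <- S / 2 + stats::runif(1, -0.1, 0.1) * S
  cx <- S / 2 + stats::runif(1, -0.1, 0.1) * S
  r0 <- frac * S / 2
  kLow <- 2:5
  aLow <- stats::rnorm(length(kLow), 0, 0.06)
  phLow <- stats::runif(length(kLow), 0, 2 * pi)
  phAsym <- stats::runif(1, 0, 2 * pi)
  kHigh <- 9:14
  aHigh <- stats::rnorm(length(kHigh), 0, 1)
  phHigh <- stats::runif(length(kHigh), 0, 2 * pi)
  yy <- matrix(seq_len(S), S, S) - cy
  xx <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  th <- atan2(yy, xx)
  rr <- sqrt(yy^2 + xx^2)
  rad <- r0 * (1 + asymAmp * cos(th + phAsym))
  for (i in seq_along(kLow)) rad <- rad + r0 * aLow[i] * cos(kLow[i] * th + phLow[i])
  for (i in seq_along(kHigh)) rad <- rad + r0 * borderAmp * aHigh[i] * cos(kHigh[i] * th + phHigh[i])
  list(inside = (rr <= rad) + 0, cy = cy, cx = cx, r0 = r0, th = th, rr = rr)
}

# Each overlay returns list(delta = S x S x 3 additive field, support =
# logical S x S of touched pixels). Overlays are additive in intensity
# space so the metadata -> pixels link is local and unit-testable.
overlayPigmentNetwork <- function(S, region, amp, atypical) {
  p <- max(3, S / 14)
  ph <- stats::runif(2, 0, 2 * pi)
  y <- matrix(seq_len(S), S, S); x <- t(y)
  warp <- if (atypical) ebBlurGray(matrix(stats::runif(S * S, -1, 1), S), S / 10) * p else 0
  g <- sin(2 * pi * (x + warp) / p + ph[1]) * sin(2 * pi * (y - warp) / p + ph[2])
  sup <- region$inside == 1 & g > 0.55
  delta <- array(0, c(S, S, 3))
  for (c in 1:3) delta[, , c] <- -amp * sup
  list(delta = delta, support = sup)
}

overlayDots <- function(S, region, amp, many) {
  n <- if (many) 18L else 6L
  inside <- which(region$inside == 1 & region$rr < 0.8 * region$r0)
  if (length(inside) == 0L) inside <- which(region$inside == 1)
  ctr <- inside[sample.int(length(inside), min(n, length(inside)), replace = TRUE)]
  rad <- stats::runif(length(ctr), S / 50 + 0.8, S / 25 + 1)
  sup <- matrix(FALSE, S, S)
  y <- matrix(seq_len(S), S, S); x <- t(y)
  for (i in seq_along(ctr)) {
    cy <- (ctr[i] - 1) %% S + 1
    cx <- (ctr[i] - 1) %/% S + 1
    sup <- sup | ((y - cy)^2 + (x - cx)^2 <= rad[i]^2)
  }
  sup <- sup & region$inside == 1
  delta <- array(0, c(S, S, 3))
  for (c in 1:3) delta[, , c] <- -amp * sup
  list(delta = delta, support = sup)
}

overlayStreaks <- function(S, region, amp, irregular) {
  m <- if (irregular) 14L else 8L
  ang <- stats::runif(m, 0, 2 * pi)
  width <- stats::runif(m, 0.08, if (irregular) 0.25 else 0.14)
  sup <- matrix(FALSE, S, S)
  for (i in seq_len(m)) {
    dth <- abs(((region$th - ang[i] + pi) %% (2 * pi)) - pi)
    sup <- sup | (dth < width[i] & region$rr > 0.72 * region$r0 &
                    region$rr < 1.28 * region$r0)
  }
  delta <- array(0, c(S, S, 3))
  for (c in 1:3) delta[, , c] <- -amp * sup
  list(delta = delta, support = sup)
}

overlayRegression <- function(S, region, amp, extensive) {
  n <- if (extensive) 5L else 2L
  inside <- which(region$inside == 1)
  ctr <- inside[sample.int(length(inside), min(n, length(inside)), replace = TRUE)]
  f <- matrix(0, S, S)
  y <- matrix(seq_len(S), S, S); x <- t(y)
  for (i in seq_along(ctr)) {
    cy <- (ctr[i] - 1) %% S + 1
    cx <- (ctr[i] - 1) %/% S + 1
    r <- stats::runif(1, S / 14, S / 8)
    f <- f + exp(-((y - cy)^2 + (x - cx)^2) / (2 * r^2))
  }
  f <- f * (region$inside == 1)
  delta <- array(0, c(S, S, 3))
  for (c in 1:3) delta[, , c] <- amp * f
  list(delta = delta, support = f > 1e-3)
}

overlayVeil <- function(S, region, amp) {
  sup <- region$inside == 1
  delta <- array(0, c(S, S, 3))
  delta[, , 1] <- -amp / 2 * sup
  delta[, , 3] <- amp * sup
  list(delta = delta, support = sup)
}

overlayColorFlag <- function(S, region, amp, signature) {
  inside <- which(region$inside == 1)
  ctr <- inside[sample.int(length(inside), 1L)]
  cy <- (ctr - 1) %% S + 1
  cx <- (ctr - 1) %/% S + 1
  r <- stats::runif(1, S / 12, S / 7)
  y <- matrix(seq_len(S), S, S); x <- t(y)
  f <- exp(-((y - cy)^2 + (x - cx)^2) / (2 * r^2)) * (region$inside == 1)
  delta <- array(0, c(S, S, 3))
  for (c in 1:3) delta[, , c] <- amp * signature[c] * f
  list(delta = delta, support = f > 1e-3)
}

colorSignatures <- function() {
  list(white = c(1, 1, 1), red = c(1, -0.5, -0.5),
       light_brown = c(0.4, 0.1, -0.4), dark_brown = c(-0.6, -0.8, -1),
       blue_gray = c(-0.4, -0.2, 0.8), black = c(-1, -1, -1))
}

#' Generate one synthetic lesion sample
#'
#' Fully deterministic given `(cfg@seed, index)`: every random component
#' (metadata draw, outline, background, each overlay, noise) runs on its own
#' derived stream, so toggling one metadata attribute perturbs only the
#' pixels that attribute renders.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param index sample index within the dataset (drives the sample stream).
#' @param schema a [MetadataSchema-class]; the default 29-column schema.
#' @param metadata optional metadata vector overriding the random draw
#'   (used to study the metadata-to-pixel coupling).
#' @param details if `TRUE`, also return the per-attribute overlay supports.
#' @return a [LesionSample-class], or (with `details = TRUE`) a list with
#'   elements `sample` and `supports`.
#' @export
generateSample <- function(cfg, index = 1L, schema = defaultMetadataSchema(),
                           metadata = NULL, details = FALSE) {
  validObject(cfg)
  S <- cfg@imageSize
  base <- sampleSeedFor(cfg@seed, index)
  if (is.null(metadata))
    metadata <- withSeed(subSeed(base, "meta"), sampleMetadata(cfg, schema))
  validateMetadata(metadata, schema)

  diagCat <- activeCategory(metadata, schema, "diagnosis")
  asymCat <- activeCategory(metadata, schema, "asymmetry")
  bordCat <- activeCategory(metadata, schema, "border_irregularity")
  asymAmp <- c(symmetric = 0, mild = 0.12, severe = 0.25)[asymCat]
  bordAmp <- c(regular = 0, mild = 0.03, severe = 0.07)[bordCat]

  region <- NULL
  for (attempt in 1:10) {
    region <- withSeed(subSeed(base, paste0("shape", attempt)), {
      frac <- stats::runif(1, cfg@lesionFracRange[1], cfg@lesionFracRange[2])
      lesionRegion(S, frac, asymAmp, bordAmp)
    })
    if (sum(region$inside) >= 9) break
    if (attempt == 10) stop("degenerate lesion (area < 9 px) after 10 resamples")
  }
  mask <- region$inside  # exact indicator, before any blurring

  bg <- withSeed(subSeed(base, "bg"), {
    tex <- ebBlurGray(matrix(stats::runif(S * S, -1, 1), S, S), max(2, S / 16))
    mx <- max(abs(tex)); if (mx > 0) tex <- tex / mx
    0.55 + 0.06 * tex
  })

  # Contrast polarity and magnitude. In the standard task melanomas are
  # slightly higher-contrast; in the ambiguous task the magnitude is fixed
  # and only the polarity carries the diagnosis signal.
  darker <- TRUE
  cEff <- cfg@contrast
  if (cfg@polarityByDiagnosis) {
    darker <- identical(diagCat, "melanoma")
  } else {
    cEff <- cfg@contrast *
      c(common_nevus = 0.9, atypical_nevus = 1.0, melanoma = 1.1)[diagCat]
  }
  alpha <- if (cfg@sigmaB > 0) ebBlurGray(mask, cfg@sigmaB) else mask
  intensity <- if (darker) bg * (1 - cEff * alpha) else bg * (1 + cEff * alpha)

  tone <- c(0.95, 0.78, 0.66)
  img <- array(0, c(S, S, 3))
  for (c in 1:3) img[, , c] <- intensity * tone[c]

  amp <- cfg@textureAmp
  supports <- list()
  addOverlay <- function(name, ov) {
    img <<- img + ov$delta
    supports[[name]] <<- ov$support
  }
  pn <- activeCategory(metadata, schema, "pigment_network")
  if (pn != "absent" && amp[["pigment_network"]] > 0)
    addOverlay("pigment_network", withSeed(subSeed(base, "pignet"),
      overlayPigmentNetwork(S, region, amp[["pigment_network"]], pn == "atypical")))
  dg <- activeCategory(metadata, schema, "dots_globules")
  if (dg != "absent" && amp[["dots_globules"]] > 0)
    addOverlay("dots_globules", withSeed(subSeed(base, "dots"),
      overlayDots(S, region, amp[["dots_globules"]], dg == "many")))
  st <- activeCategory(metadata, schema, "streaks")
  if (st != "absent" && amp[["streaks"]] > 0)
    addOverlay("streaks", withSeed(subSeed(base, "streaks"),
      overlayStreaks(S, region, amp[["streaks"]], st == "irregular")))
  rg <- activeCategory(metadata, schema, "regression")
  if (rg != "absent" && amp[["regression"]] > 0)
    addOverlay("regression", withSeed(subSeed(base, "regression"),
      overlayRegression(S, region, amp[["regression"]], rg == "extensive")))
  if (activeCategory(metadata, schema, "blue_whitish_veil") == "present" &&
      amp[["blue_whitish_veil"]] > 0)
    addOverlay("blue_whitish_veil", overlayVeil(S, region, amp[["blue_whitish_veil"]]))
  colIdx <- schemaGroupIndex(schema)[["colors"]]
  sigs <- colorSignatures()
  colCats <- schema@groups[[which(vapply(schema@groups, function(g) g$name,
                                         character(1)) == "colors")]]$categories
  for (j in seq_along(colIdx)) {
    if (metadata[colIdx[j]] == 1 && amp[["colors"]] > 0) {
      sig <- sigs[[colCats[j]]]
      if (is.null(sig)) sig <- c(-0.5, -0.5, -0.5)
      addOverlay(paste0("colors.", colCats[j]),
                 withSeed(subSeed(base, paste0("color", j)),
                          overlayColorFlag(S, region, amp[["colors"]], sig)))
    }
  }

  if (cfg@sigmaN > 0)
    img <- img + withSeed(subSeed(base, "noise"),
                          array(stats::rnorm(S * S * 3, 0, cfg@sigmaN), c(S, S, 3)))
  smp <- lesionSample(sprintf("syn%05d", index), clip01(img), mask, metadata,
                      schema = schema)
  if (details) list(sample = smp, supports = supports) else smp
}

#' Generate a full synthetic dataset
#'
#' @param cfg a [GeneratorConfig-class].
#' @param schema a [MetadataSchema-class].
#' @param dir optional output directory; when given, images, masks,
#'   `metadata.csv` and a `manifest.yaml` (full config + seed + package
#'   version) are written in the on-disk layout of [writeDataset()].
#' @return list of [LesionSample-class] of length `cfg@nSamples`.
#' @export
generateDataset <- function(cfg, schema = defaultMetadataSchema(), dir = NULL) {
  samples <- lapply(seq_len(cfg@nSamples), function(i)
    generateSample(cfg, i, schema))
  if (!is.null(dir)) {
    writeDataset(samples, dir, schema)
    yaml::write_yaml(list(package = "LesionSegUQ",
                          version = as.character(utils::packageVersion("LesionSegUQ")),
                          seed = cfg@seed,
                          config = generatorConfigAsList(cfg)),
                     file.path(dir, "manifest.yaml"))
  }
  samples
}

generatorConfigAsList <- function(cfg) {
  list(imageSize = cfg@imageSize, nSamples = cfg@nSamples,
       lesionFracRange = cfg@lesionFracRange, sigmaB = cfg@sigmaB,
       contrast = cfg@contrast, prevalence = cfg@prevalence,
       textureAmp = as.list(cfg@textureAmp), sigmaN = cfg@sigmaN,
       polarityByDiagnosis = cfg@polarityByDiagnosis, seed = cfg@seed)
}

#' Rebuild a generator configuration from a dataset manifest
#'
#' @param path path to a `manifest.yaml` written by [generateDataset()].
#' @return the [GeneratorConfig-class] that produced the dataset.
#' @export
generatorConfigFromManifest <- function(path) {
  y <- yaml::read_yaml(path)$config
  generatorConfig(imageSize = y$imageSize, nSamples = y$nSamples,
                  lesionFracRange = unlist(y$lesionFracRange),
                  sigmaB = y$sigmaB, contrast = y$contrast,
                  prevalence = lapply(y$prevalence, unlist),
                  textureAmp = unlist(y$textureAmp), sigmaN = y$sigmaN,
                  polarityByDiagnosis = y$polarityByDiagnosis, seed = y$seed)
}

#' Derive the metadata-resolvable ambiguous segmentation task
#'
#' Returns a copy of `cfg` in which the lesion/background contrast is small
#' (0.12), the boundary heavily blurred, pixel noise is on the order of the
#' contrast, texture overlays are disabled and the contrast polarity is
#' tied to the diagnosis (darker iff melanoma, lighter otherwise, with
#' melanoma prevalence 0.5). Pixel intensities alone are then weakly
#' informative about where the lesion boundary is and in which direction
#' the lesion deviates, while the diagnosis attribute resolves the
#' polarity — the regime in which metadata fusion should help most.
#'
#' @param cfg a [GeneratorConfig-class] to derive from.
#' @return a modified [GeneratorConfig-class].
#' @export
makeAmbiguousTask <- function(cfg = generatorConfig()) {
  cfg@contrast <- 0.12
  cfg@sigmaB <- max(cfg@sigmaB, 1.5)
  cfg@sigmaN <- 0.08
  cfg@polarityByDiagnosis <- TRUE
  cfg@prevalence$diagnosis <- c(0.25, 0.25, 0.5)
  cfg@textureAmp[] <- 0
  validObject(cfg)
  cfg
}
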