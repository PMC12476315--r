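#' Monte Carlo Dropout prediction ensemble
#'
#' Runs `T` stochastic forward passes with dropout sampling active at
#' inference time, approximating draws from the posterior predictive
#' distribution. Each pass takes an independent seeded dropout draw; the
#' whole ensemble is deterministic for a fixed seed.
#'
#' @param model a [MetaUNet-class] built with `bayesian = TRUE`.
#' @param sample a [LesionSample-class].
#' @param T number of stochastic passes (default 10).
#' @param seed integer seed of the dropout draws.
#' @return a [PredictionEnsemble-class] (`T x H x W x 2` probabilities;
#'   class 1 = lesion).
#' @export
mcdPredict <- function(model, sample, T = 10L, seed = 1L) {
  if (!model@config@bayesian)
    stop("model was built with bayesian = FALSE; rebuild with bayesian = TRUE ",
         "to enable Monte Carlo Dropout")
  bt <- samplesToBatch(list(sample))
  H <- dim(bt$x)[1]; W <- dim(bt$x)[2]
  probs <- array(0, c(T, H, W, 2L))
  withSeed(seed, {
    for (t in seq_len(T)) {
      fw <- nnForward(model, bt$x, bt$meta, stochastic = TRUE)
      p <- fw$probs[, , 1L, 1L]
      probs[t, , , 1L] <- p
      probs[t, , , 2L] <- 1 - p
    }
  })
  new("PredictionEnsemble", probs = probs, id = sample@id,
      seed = as.integer(seed))
}

#' @describeIn PredictionEnsemble-class ensemble summary
#' @param object a `PredictionEnsemble`.
#' @export
setMethod("show", "PredictionEnsemble", function(object) {
  d <- dim(object@probs)
  cat(sprintf("PredictionEnsemble '%s': T = %d passes over %d x %d pixels\n",
              object@id, d[1], d[2], d[3]))
  invisible(NULL)
})

ensMean <- function(ensemble) {
  # mean class probabilities over passes: H x W x 2
  apply(ensemble@probs, c(2, 3, 4), mean)
}

entropyOf <- function(p) {
  # elementwise -p log2 p with clipping inside the log
  -p * log2(pmax(p, 1e-12))
}

#' Pixel-wise confidence map
#'
#' `C(px) = max_c mean_t p_t(c | px)`: the probability of the most likely
#' class under the ensemble-mean prediction. Ranges from `1/n_classes`
#' (maximally ambiguous) to 1.
#'
#' @param ensemble a [PredictionEnsemble-class].
#' @return H x W matrix.
#' @export
confidenceMap <- function(ensemble) {
  pbar <- ensMean(ensemble)
  pmax(pbar[, , 1L], pbar[, , 2L])
}

#' Pixel-wise predictive entropy map (bits)
#'
#' Entropy of the ensemble-mean class distribution,
#' `H(px) = -sum_c pbar(c) log2 pbar(c)`; captures total (aleatoric +
#' epistemic) uncertainty. Bounded by `log2(n_classes)` = 1 bit here.
#'
#' @param ensemble a [PredictionEnsemble-class].
#' @return H x W matrix.
#' @export
entropyMap <- function(ensemble) {
  pbar <- ensMean(ensemble)
  entropyOf(pbar[, , 1L]) + entropyOf(pbar[, , 2L])
}

#' Pixel-wise mutual information map (bits)
#'
#' `MI(px) = H(pbar) - mean_t H(p_t)`: the entropy of the mean minus the
#' mean per-pass entropy, isolating the epistemic (disagreement) part of
#' the predictive uncertainty. Zero when all passes agree.
#'
#' @param ensemble a [PredictionEnsemble-class] with `T >= 2`.
#' @return H x W matrix.
#' @export
mutualInformationMap <- function(ensemble) {
  if (dim(ensemble@probs)[1] < 2L) stop("mutual information requires T >= 2")
  perPass <- entropyOf(ensemble@probs[, , , 1L, drop = FALSE]) +
    entropyOf(ensemble@probs[, , , 2L, drop = FALSE])
  entropyMap(ensemble) - apply(perPass[, , , 1L, drop = FALSE], c(2, 3), mean)
}

#' Pixel-wise expected pairwise KL divergence map (bits)
#'
#' The default `variant = "pairwise"` averages `KL(p_i || p_j)` over all
#' ordered pairs `i != j` of passes. `variant = "mean"` instead averages
#' `KL(p_t || pbar)`, the divergence of each pass from the ensemble mean.
#' Both are zero when all passes agree.
#'
#' @param ensemble a [PredictionEnsemble-class] with `T >= 2`.
#' @param variant `"pairwise"` (default) or `"mean"`.
#' @return H x W matrix.
#' @export
epklMap <- function(ensemble, variant = c("pairwise", "mean")) {
  variant <- match.arg(variant)
  P <- ensemble@probs
  T <- dim(P)[1]
  if (T < 2L) stop("EPKL requires T >= 2")
  lp <- log2(pmax(P, 1e-12))
  if (variant == "mean") {
    pbar <- ensMean(ensemble)
    lbar <- log2(pmax(pbar, 1e-12))
    out <- matrix(0, dim(P)[2], dim(P)[3])
    for (t in seq_len(T)) {
      for (c in 1:2) {
        pt <- P[t, , , c]
        out <- out + pt * (log2(pmax(pt, 1e-12)) - lbar[, , c])
      }
    }
    return(out / T)
  }
  # sum_{i != j} KL(p_i || p_j) expands to
  # (T-1) * sum_i sum_c p_i log p_i  -  sum_c [ (sum_i p_i)(sum_j log p_j)
  #                                             - sum_i p_i log p_i ]
  out <- 0
  for (c in 1:2) {
    pc <- P[, , , c]; lc <- lp[, , , c]
    selfTerm <- apply(pc * lc, c(2, 3), sum)
    cross <- apply(pc, c(2, 3), sum) * apply(lc, c(2, 3), sum) - selfTerm
    out <- out + (T - 1) * selfTerm - cross
  }
  out / (T * (T - 1))
}

#' Per-image uncertainty report from an ensemble
#'
#' Computes the four maps and their per-image means. Normalized means and
#' the aggregate score are filled in by [normalizeMeasures()], which needs
#' the whole evaluation cohort.
#'
#' @param ensemble a [PredictionEnsemble-class].
#' @param epklVariant passed to [epklMap()].
#' @return an [UncertaintyReport-class].
#' @export
uncertaintyReport <- function(ensemble, epklVariant = "pairwise") {
  maps <- list(C = confidenceMap(ensemble), H = entropyMap(ensemble),
               MI = mutualInformationMap(ensemble),
               EPKL = epklMap(ensemble, epklVariant))
  means <- vapply(maps, mean, numeric(1))
  new("UncertaintyReport", id = ensemble@id, maps = maps, means = means,
      normalized = c(C = NA_real_, H = NA_real_, MI = NA_real_,
                     EPKL = NA_real_),
      uTot = NA_real_, weights = c(0.4, 0.2, 0.2, 0.2), cohort = NA_character_)
}

#' @describeIn UncertaintyReport-class per-image summary
#' @param object an `UncertaintyReport`.
#' @export
setMethod("show", "UncertaintyReport", function(object) {
  cat(sprintf("UncertaintyReport '%s': meanC %.4f, meanH %.4f, meanMI %.4f, meanEPKL %.4f%s\n",
              object@id, object@means["C"], object@means["H"],
              object@means["MI"], object@means["EPKL"],
              if (is.na(object@uTot)) " (not yet normalized)"
              else sprintf(", U_tot %.4f", object@uTot)))
  invisible(NULL)
})

#' Aggregate uncertainty score from normalized measure means
#'
#' `U_tot = alpha * C - beta * H + gamma * MI - delta * EPKL` with default
#' weights (0.4, 0.2, 0.2, 0.2). The sign pattern is kept exactly as the
#' formula prints it; note that with these signs higher confidence raises
#' the score, so the ranking direction is an explicit choice in
#' [rankByUncertainty()].
#'
#' @param normC,normH,normMI,normEPKL normalized per-image means in
#'   `[0, 1]`.
#' @param weights numeric `(alpha, beta, gamma, delta)`, all non-negative.
#' @return scalar score.
#' @examples
#' aggregateScore(0.5, 0.5, 0.5, 0.5)  # 0.1
#' @export
aggregateScore <- function(normC, normH, normMI, normEPKL,
                           weights = c(0.4, 0.2, 0.2, 0.2)) {
  if (any(weights < 0)) stop("aggregation weights must be non-negative")
  weights[1] * normC - weights[2] * normH + weights[3] * normMI -
    weights[4] * normEPKL
}

#' Min-max normalize measure means across a cohort and score each image
#'
#' Each of the four measures is min-max normalized to `[0, 1]` across the
#' cohort of reports (a degenerate cohort with max = min maps to 0), the
#' aggregate score is computed per image, and every report is stamped with
#' a cohort fingerprint so scores from different normalization cohorts
#' cannot be compared or ranked together.
#'
#' @param reports list of [UncertaintyReport-class] from one evaluation
#'   cohort.
#' @param weights aggregation weights, see [aggregateScore()].
#' @return the list of reports with `normalized`, `uTot`, `weights` and
#'   `cohort` filled in.
#' @export
normalizeMeasures <- function(reports, weights = c(0.4, 0.2, 0.2, 0.2)) {
  if (length(reports) == 0L) stop("empty cohort")
  ids <- vapply(reports, function(r) r@id, character(1))
  fp <- paste(sort(ids), collapse = "|")
  measures <- c("C", "H", "MI", "EPKL")
  m <- sapply(measures, function(nm)
    vapply(reports, function(r) r@means[[nm]], numeric(1)))
  m <- matrix(m, nrow = length(reports),
              dimnames = list(NULL, measures))
  norm <- m
  for (nm in measures) {
    rng <- range(m[, nm])
    norm[, nm] <- if (diff(rng) < 1e-12) 0 else (m[, nm] - rng[1]) / diff(rng)
  }
  lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    r@normalized <- norm[i, ]
    r@weights <- weights
    r@uTot <- aggregateScore(norm[i, "C"], norm[i, "H"], norm[i, "MI"],
                             norm[i, "EPKL"], weights)
    r@cohort <- fp
    r
  })
}

#' Rank images by aggregate uncertainty score
#'
#' Ids are sorted by `U_tot` (descending by default, so that with the
#' printed sign convention the most *confident* images rank first; set
#' `decreasing = FALSE` to surface the least confident). Ties break
#' lexicographically by id. All reports must come from one
#' [normalizeMeasures()] cohort.
#'
#' @param reports list of scored [UncertaintyReport-class].
#' @param k optionally return only the top `k` ids.
#' @param decreasing sort direction.
#' @return character vector of ids.
#' @export
rankByUncertainty <- function(reports, k = NULL, decreasing = TRUE) {
  fps <- vapply(reports, function(r) r@cohort, character(1))
  if (anyNA(fps) || length(unique(fps)) != 1L)
    stop("reports must be scored on one shared normalization cohort")
  ids <- vapply(reports, function(r) r@id, character(1))
  sc <- vapply(reports, function(r) r@uTot, numeric(1))
  ord <- order(if (decreasing) -sc else sc, ids)
  out <- ids[ord]
  if (!is.null(k)) out <- utils::head(out, k)
  out
}

#' Write uncertainty maps and a cohort summary table
#'
#' Each map is written as a single-channel 32-bit TIFF
#' (`<id>_<measure>.tif`) plus an 8-bit colormapped PNG for visual
#' inspection; the cohort summary (per-image means, normalized means,
#' `U_tot`) as `uncertainty_summary.csv`.
#'
#' @param reports list of scored [UncertaintyReport-class].
#' @param dir output directory.
#' @return invisibly the summary data.frame.
#' @export
writeUncertaintyOutputs <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pal <- grDevices::hcl.colors(256, "viridis")
  for (r in reports) {
    for (nm in names(r@maps)) {
      m <- r@maps[[nm]]
      tiffPath <- file.path(dir, sprintf("%s_%s.tif", r@id, nm))
      EBImage::writeImage(EBImage::Image(t(m)), tiffPath, type = "tiff",
                          bits.per.sample = 32L)
      rng <- range(m)
      idx <- if (diff(rng) < 1e-12) matrix(1L, nrow(m), ncol(m))
             else matrix(findInterval(m, seq(rng[1], rng[2], length.out = 257),
                                      all.inside = TRUE), nrow(m))
      rgb <- grDevices::col2rgb(pal[idx]) / 255
      arr <- array(0, c(nrow(m), ncol(m), 3L))
      for (c in 1:3) arr[, , c] <- matrix(rgb[c, ], nrow(m))
      png::writePNG(arr, file.path(dir, sprintf("%s_%s.png", r@id, nm)))
    }
  }
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(id = r@id, meanC = r@means[["C"]], meanH = r@means[["H"]],
               meanMI = r@means[["MI"]], meanEPKL = r@means[["EPKL"]],
               normC = r@normalized[["C"]], normH = r@normalized[["H"]],
               normMI = r@normalized[["MI"]], normEPKL = r@normalized[["EPKL"]],
               uTot = r@uTot)))
  utils::write.csv(df, file.path(dir, "uncertainty_summary.csv"),
                   row.names = FALSE)
  invisible(df)
}
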