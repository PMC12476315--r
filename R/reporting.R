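#' Evaluate a trained model on a test cohort
#'
#' Computes per-image IoU and Dice (as percentages) for predictions
#' binarized at 0.5, plus a mean +/- standard-deviation summary in the
#' usual benchmark-table style. Dispersion defaults to the population
#' standard deviation (`sampleSD = TRUE` switches to the sample sd).
#'
#' @param model a [MetaUNet-class].
#' @param samples non-empty list of [LesionSample-class].
#' @param sampleSD use the n-1 denominator for the summary sd.
#' @param path optional CSV path; per-image rows plus one summary row.
#' @return data.frame with columns id, iou, dice (percent); the summary
#'   row (`id = "mean±sd"`) is attached as attribute `"summary"` and
#'   appended to the CSV.
#' @export
evaluateModel <- function(model, samples, sampleSD = FALSE, path = NULL) {
  if (length(samples) == 0L) stop("empty test cohort")
  preds <- predictModel(model, samples)
  df <- do.call(rbind, lapply(seq_along(samples), function(i)
    data.frame(id = samples[[i]]@id,
               iou = 100 * iouMetric(preds[[i]], samples[[i]]@mask),
               dice = 100 * diceMetric(preds[[i]], samples[[i]]@mask))))
  summ <- evalSummary(df$iou, df$dice, sampleSD)
  attr(df, "summary") <- summ
  if (!is.null(path)) {
    out <- rbind(data.frame(id = df$id, iou = sprintf("%.2f", df$iou),
                            dice = sprintf("%.2f", df$dice)), summ)
    utils::write.csv(out, path, row.names = FALSE)
  }
  df
}

# Mean +/- sd summary row in benchmark-table style (percent, 2 decimals).
evalSummary <- function(iou, dice, sampleSD = FALSE) {
  popSD <- function(x) sqrt(mean((x - mean(x))^2))
  dev <- if (sampleSD) stats::sd else popSD
  data.frame(id = "mean±sd",
             iou = sprintf("%.2f ± %.2f", mean(iou), dev(iou)),
             dice = sprintf("%.2f ± %.2f", mean(dice), dev(dice)))
}

#' Per-attribute IoU breakdown
#'
#' For every attribute category of the schema (one-hot categories, and
#' present/absent for binary flags) the distribution of per-image IoU over
#' the images in that category: count, median, quartiles and the number of
#' outliers under the 1.5 IQR rule — the tabular form of a per-attribute
#' boxplot. Categories with zero images are emitted with count 0 and NA
#' statistics.
#'
#' @param perImage data.frame with columns `id` and `iou` (e.g. from
#'   [evaluateModel()]).
#' @param metadata data.frame with column `id` plus the schema columns
#'   (as written by [writeDataset()]).
#' @param schema a [MetadataSchema-class].
#' @return data.frame with columns group, category, n, median, q1, q3,
#'   nOutliers.
#' @export
reportAttributes <- function(perImage, metadata, schema) {
  if (!all(perImage$id %in% metadata$id))
    stop("metadata is missing rows for some evaluated ids")
  md <- metadata[match(perImage$id, metadata$id), , drop = FALSE]
  cols <- schemaColumnNames(schema)
  rows <- list()
  addRow <- function(group, category, sel) {
    v <- perImage$iou[sel]
    if (length(v) == 0L) {
      rows[[length(rows) + 1]] <<- data.frame(group = group,
        category = category, n = 0L, median = NA_real_, q1 = NA_real_,
        q3 = NA_real_, nOutliers = NA_integer_)
      return(invisible())
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    out <- sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr)
    rows[[length(rows) + 1]] <<- data.frame(group = group, category = category,
      n = length(v), median = q[2], q1 = q[1], q3 = q[3],
      nOutliers = as.integer(out))
  }
  for (g in schema@groups) {
    if (g$type == "onehot") {
      for (cat in g$categories)
        addRow(g$name, cat, md[[paste(g$name, cat, sep = ".")]] == 1)
    } else {
      for (cat in g$categories) {
        col <- paste(g$name, cat, sep = ".")
        addRow(g$name, paste0(cat, "=present"), md[[col]] == 1)
        addRow(g$name, paste0(cat, "=absent"), md[[col]] == 0)
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare two models on a shared test cohort
#'
#' Takes one report per model — a per-image table of IoU, Dice and
#' aggregate uncertainty score on the *same* cohort (each model normalized
#' over that cohort separately) — and produces the side-by-side means plus
#' per-image paired differences.
#'
#' @param reportA,reportB lists with elements `model` (character label)
#'   and `table` (data.frame with columns id, iou, dice, uTot).
#' @return list with `models` (2-row data.frame: model, meanIoU, meanDice,
#'   meanUTot) and `paired` (data.frame of per-image differences A - B).
#' @export
compareModels <- function(reportA, reportB) {
  ta <- reportA$table[order(reportA$table$id), ]
  tb <- reportB$table[order(reportB$table$id), ]
  if (!identical(ta$id, tb$id))
    stop("model reports cover different cohorts")
  models <- do.call(rbind, lapply(list(reportA, reportB), function(r)
    data.frame(model = r$model, meanIoU = mean(r$table$iou),
               meanDice = mean(r$table$dice), meanUTot = mean(r$table$uTot))))
  paired <- data.frame(id = ta$id, dIoU = ta$iou - tb$iou,
                       dDice = ta$dice - tb$dice, dUTot = ta$uTot - tb$uTot)
  list(models = models, paired = paired)
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the configuration objects, seeds and package version needed to
#' reproduce a run bit-for-bit.
#'
#' @param path output YAML path.
#' @param ... named configuration entries (S4 config objects are
#'   serialized slot-wise).
#' @return invisibly `path`.
#' @export
writeRunManifest <- function(path, ...) {
  ser <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(x)
    sl <- lapply(slotNames(x), function(nm) ser(slot(x, nm)))
    names(sl) <- slotNames(x)
    sl
  }
  entries <- lapply(list(...), function(x) {
    if (isS4(x)) ser(x)
    else if (is.matrix(x)) as.data.frame(x)
    else x
  })
  yaml::write_yaml(c(list(package = "LesionSegUQ",
                          version = as.character(utils::packageVersion("LesionSegUQ"))),
                     entries), path)
  invisible(path)
}
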