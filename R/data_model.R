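#' Construct a lesion sample
#'
#' @param id character identifier.
#' @param image numeric H x W x 3 array in `[0, 1]`.
#' @param mask numeric H x W matrix in `{0, 1}`.
#' @param metadata numeric metadata vector.
#' @param schema optional [MetadataSchema-class]; when supplied, the
#'   metadata vector is validated against its one-hot constraints.
#' @return a [LesionSample-class].
#' @export
lesionSample <- function(id, image, mask, metadata, schema = NULL) {
  if (!is.null(schema)) validateMetadata(metadata, schema)
  new("LesionSample", id = id, image = image, mask = mask,
      metadata = as.numeric(metadata))
}

#' @describeIn LesionSample-class one-line summary
#' @param object a `LesionSample`.
#' @export
setMethod("show", "LesionSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("LesionSample '%s': %d x %d image, lesion area %d px, %d metadata columns\n",
              object@id, d[1], d[2], sum(object@mask), length(object@metadata)))
  invisible(NULL)
})

# Decode a raster file to a numeric array in [0, 1]. PNG goes through the
# png package; anything else (JPEG) through EBImage.
readRaster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    a <- if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
  }
  a
}

toRGB <- function(a) {
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a
}

#' Read one sample from image + mask files and a metadata row
#'
#' The image is rescaled to `[0, 1]` (8-bit 255 maps to 1.0) and grayscale
#' images are replicated to three channels. The mask is normalized by its
#' maximum and binarized at 0.5, so both 0/1 and 0/255 encodings are
#' accepted. Masks must be PNG; images may be PNG or JPEG.
#'
#' @param imagePath,maskPath raster file paths.
#' @param metadataRow numeric vector (or 1-row data.frame) with one entry
#'   per schema column.
#' @param schema a [MetadataSchema-class].
#' @param id sample identifier; defaults to the image file stem.
#' @return a [LesionSample-class].
#' @export
readSample <- function(imagePath, maskPath, metadataRow, schema,
                       id = sub("\\.[^.]+$", "", basename(imagePath))) {
  if (!grepl("\\.png$", maskPath, ignore.case = TRUE))
    stop("masks must be PNG files: ", maskPath)
  image <- toRGB(readRaster(imagePath))
  m <- readRaster(maskPath)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  if (!all(dim(image)[1:2] == dim(m)))
    stop(sprintf("image shape %dx%d does not match mask shape %dx%d",
                 dim(image)[1], dim(image)[2], nrow(m), ncol(m)))
  mx <- max(m)
  if (mx > 0) m <- m / mx
  mask <- (m >= 0.5) + 0
  if (is.data.frame(metadataRow)) metadataRow <- as.numeric(metadataRow[1, ])
  lesionSample(id, image, mask, metadataRow, schema = schema)
}

#' Write one sample to disk in the package's on-disk layout
#'
#' Writes `images/<id>.png` and `masks/<id>.png` under `dir`. Metadata is
#' written separately by [writeDataset()].
#'
#' @param sample a [LesionSample-class].
#' @param dir output directory (created if needed).
#' @return invisibly the two file paths.
#' @export
writeSample <- function(sample, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ip <- file.path(dir, "images", paste0(sample@id, ".png"))
  mp <- file.path(dir, "masks", paste0(sample@id, ".png"))
  png::writePNG(sample@image, ip)
  png::writePNG(sample@mask, mp)
  invisible(c(image = ip, mask = mp))
}

#' Resize a sample to a square size
#'
#' The image is resized bilinearly; the mask with nearest-neighbour
#' interpolation so it stays strictly binary. Metadata is unchanged.
#'
#' @param sample a [LesionSample-class].
#' @param size target edge length in pixels (>= 16); 224 matches the
#'   reference configuration.
#' @return the resized [LesionSample-class].
#' @export
resizeSample <- function(sample, size = 224L) {
  size <- as.integer(size)
  if (size < 16L) stop("size must be >= 16")
  d <- dim(sample@image)
  if (d[1] == size && d[2] == size) return(sample)
  image <- array(0, dim = c(size, size, 3L))
  for (c in 1:3) image[, , c] <- ebResizeGray(sample@image[, , c], size, size)
  mask <- ebResizeGray(sample@mask, size, size, bilinear = FALSE)
  lesionSample(sample@id, clip01(image), mask, sample@metadata)
}

#' Split sample ids into train/validation/test partitions
#'
#' Ids are shuffled by a seeded RNG and partitioned with largest-remainder
#' rounding, so partition sizes sum exactly to the input size and are
#' deterministic for a fixed seed.
#'
#' @param ids character vector of sample ids.
#' @param ratios numeric length-3 proportions summing to 1 (default
#'   70:10:20).
#' @param seed integer seed.
#' @return a [DatasetSplit-class].
#' @examples
#' s <- splitDataset(sprintf("im%03d", 1:200), seed = 1)
#' lengths(list(s@train, s@val, s@test))  # 140 20 40
#' @export
splitDataset <- function(ids, ratios = c(0.70, 0.10, 0.20), seed = 1L) {
  if (length(ids) == 0L) stop("ids must be non-empty")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  if (length(ids) < 3L) stop("need at least as many ids as partitions")
  n <- length(ids)
  exact <- n * ratios
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    # largest fractional remainder first; ties go to the earlier partition
    ord <- order(-(exact - sizes), seq_along(ratios))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  shuffled <- withSeed(seed, sample(ids))
  ends <- cumsum(sizes)
  new("DatasetSplit",
      train = shuffled[seq_len(sizes[1])],
      val = if (sizes[2] > 0) shuffled[(ends[1] + 1):ends[2]] else character(0),
      test = if (sizes[3] > 0) shuffled[(ends[2] + 1):ends[3]] else character(0),
      seed = as.integer(seed))
}

#' @describeIn DatasetSplit-class partition sizes
#' @param object a `DatasetSplit`.
#' @export
setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit (seed %d): train %d / val %d / test %d\n",
              object@seed, length(object@train), length(object@val),
              length(object@test)))
  invisible(NULL)
})

#' Write a list of samples as an on-disk dataset
#'
#' Layout: `images/<id>.png`, `masks/<id>.png` and `metadata.csv` with a
#' header of `id` plus the schema-derived column names.
#'
#' @param samples list of [LesionSample-class].
#' @param dir output directory.
#' @param schema the governing [MetadataSchema-class].
#' @return invisibly `dir`.
#' @export
writeDataset <- function(samples, dir, schema) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) writeSample(s, dir)
  meta <- do.call(rbind, lapply(samples, function(s) s@metadata))
  df <- data.frame(id = vapply(samples, function(s) s@id, character(1)), meta)
  names(df) <- c("id", schemaColumnNames(schema))
  utils::write.csv(df, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an on-disk dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param schema the governing [MetadataSchema-class].
#' @return list of [LesionSample-class], in metadata.csv row order.
#' @export
readDataset <- function(dir, schema) {
  metaPath <- file.path(dir, "metadata.csv")
  if (!file.exists(metaPath)) stop("no metadata.csv under ", dir)
  df <- utils::read.csv(metaPath, check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    id <- as.character(df$id[i])
    readSample(file.path(dir, "images", paste0(id, ".png")),
               file.path(dir, "masks", paste0(id, ".png")),
               as.numeric(df[i, -1L]), schema, id = id)
  })
}
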