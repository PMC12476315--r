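#' Construct a metadata schema
#'
#' @param groups list of group descriptors (`name`, `type`, `categories`);
#'   see [MetadataSchema-class].
#' @return a validated [MetadataSchema-class] object.
#' @export
metadataSchema <- function(groups) {
  new("MetadataSchema", groups = groups)
}

#' The default 29-column dermoscopy metadata schema
#'
#' Eight one-hot attribute groups (diagnosis, asymmetry, pigment network,
#' dots/globules, streaks, regression, blue-whitish veil, border
#' irregularity; 23 columns) plus six independent binary colour flags, for a
#' total width of 29. The exact composition is a package choice: the
#' attribute families are the standard dermoscopic criteria, and the schema
#' can be replaced by any user-supplied one of matching total width.
#'
#' @return a [MetadataSchema-class] of total width 29.
#' @examples
#' schemaWidth(defaultMetadataSchema())  # 29
#' @export
defaultMetadataSchema <- function() {
  g <- function(name, type, categories)
    list(name = name, type = type, categories = categories)
  metadataSchema(list(
    g("diagnosis", "onehot", c("common_nevus", "atypical_nevus", "melanoma")),
    g("asymmetry", "onehot", c("symmetric", "mild", "severe")),
    g("pigment_network", "onehot", c("absent", "typical", "atypical")),
    g("dots_globules", "onehot", c("absent", "few", "many")),
    g("streaks", "onehot", c("absent", "regular", "irregular")),
    g("regression", "onehot", c("absent", "partial", "extensive")),
    g("blue_whitish_veil", "onehot", c("absent", "present")),
    g("border_irregularity", "onehot", c("regular", "mild", "severe")),
    g("colors", "binary",
      c("white", "red", "light_brown", "dark_brown", "blue_gray", "black"))))
}

#' Total one-hot width of a schema
#' @param schema a [MetadataSchema-class].
#' @return integer number of metadata columns.
#' @export
schemaWidth <- function(schema) {
  sum(vapply(schema@groups, function(g) length(g$categories), integer(1)))
}

#' Flat column names of a schema (`group.category`)
#' @param schema a [MetadataSchema-class].
#' @return character vector of length [schemaWidth()].
#' @export
schemaColumnNames <- function(schema) {
  unlist(lapply(schema@groups, function(g) paste(g$name, g$categories, sep = ".")),
         use.names = FALSE)
}

# Column index ranges per group, in schema order.
schemaGroupIndex <- function(schema) {
  widths <- vapply(schema@groups, function(g) length(g$categories), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  stats::setNames(mapply(seq.int, starts, ends, SIMPLIFY = FALSE),
                  vapply(schema@groups, function(g) g$name, character(1)))
}

# Embedding units of a schema: one per one-hot group, one per binary flag.
# Each unit has a name, its column indices and a vocabulary size.
schemaEmbedUnits <- function(schema) {
  idx <- schemaGroupIndex(schema)
  units <- list()
  for (g in schema@groups) {
    cols <- idx[[g$name]]
    if (g$type == "onehot") {
      units[[g$name]] <- list(cols = cols, vocab = length(g$categories))
    } else {
      for (j in seq_along(g$categories)) {
        units[[paste(g$name, g$categories[j], sep = ".")]] <-
          list(cols = cols[j], vocab = 2L)
      }
    }
  }
  units
}

#' Validate a metadata vector against a schema
#'
#' One-hot groups must contain exactly one 1 and zeros elsewhere; binary
#' flags must be 0/1. Violations raise an error naming the offending group.
#'
#' @param metadata numeric vector of length [schemaWidth()].
#' @param schema a [MetadataSchema-class].
#' @return invisibly `TRUE`.
#' @export
validateMetadata <- function(metadata, schema) {
  w <- schemaWidth(schema)
  if (length(metadata) != w)
    stop(sprintf("metadata length %d does not match schema width %d",
                 length(metadata), w))
  idx <- schemaGroupIndex(schema)
  for (g in schema@groups) {
    v <- metadata[idx[[g$name]]]
    if (!all(v %in% c(0, 1)))
      stop(sprintf("group '%s': entries must be 0/1", g$name))
    if (g$type == "onehot" && sum(v) != 1)
      stop(sprintf("group '%s': one-hot group must have exactly one active category (found %d)",
                   g$name, sum(v)))
  }
  invisible(TRUE)
}

# Integer embedding indices (1-based) for a metadata matrix (N x width):
# one column per embedding unit.
metadataToIndices <- function(meta, schema) {
  if (is.null(dim(meta))) meta <- matrix(meta, nrow = 1L)
  units <- schemaEmbedUnits(schema)
  out <- matrix(0L, nrow(meta), length(units),
                dimnames = list(NULL, names(units)))
  for (j in seq_along(units)) {
    u <- units[[j]]
    if (length(u$cols) > 1L) {
      out[, j] <- apply(meta[, u$cols, drop = FALSE], 1L, function(r) {
        k <- which(r == 1)
        if (length(k) != 1L)
          stop(sprintf("group '%s': embedding lookup needs exactly one active category",
                       names(units)[j]))
        k
      })
    } else {
      out[, j] <- as.integer(meta[, u$cols]) + 1L
    }
  }
  out
}

#' Read / write a schema as YAML
#'
#' The YAML file lists `groups`, each with `name`, `type` and `categories`.
#'
#' @param path file path.
#' @return `readSchema` returns a [MetadataSchema-class].
#' @export
readSchema <- function(path) {
  y <- yaml::read_yaml(path)
  metadataSchema(lapply(y$groups, function(g)
    list(name = g$name, type = g$type, categories = as.character(g$categories))))
}

#' @rdname readSchema
#' @param schema a [MetadataSchema-class] to serialize.
#' @export
writeSchema <- function(schema, path) {
  yaml::write_yaml(list(groups = schema@groups), path)
  invisible(path)
}

#' @describeIn MetadataSchema-class compact printout of groups and width
#' @param object a `MetadataSchema`.
#' @export
setMethod("show", "MetadataSchema", function(object) {
  cat(sprintf("MetadataSchema: %d groups, total width %d\n",
              length(object@groups), schemaWidth(object)))
  for (g in object@groups)
    cat(sprintf("  %-20s %-7s [%s]\n", g$name, g$type,
                paste(g$categories, collapse = ", ")))
  invisible(NULL)
})
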