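# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps per-sample streams independent of
# generation order.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derived from a base seed and a short tag, kept
# inside the 32-bit integer range.
subSeed <- function(base, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((as.numeric(base) %% 83492791 * 257 + h) %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# EBImage wrappers. EBImage stores images x-major; our arrays are [row, col]
# so we transpose on the way in and out. All uses here are either symmetric
# or round-tripped, so orientation is preserved.
ebResizeGray <- function(m, h, w, bilinear = TRUE) {
  img <- EBImage::Image(t(m))
  out <- EBImage::resize(img, w = w, h = h,
                         filter = if (bilinear) "bilinear" else "none")
  t(EBImage::imageData(out))
}

ebBlurGray <- function(m, sigma) {
  if (sigma <= 0) return(m)
  img <- EBImage::Image(t(m))
  t(EBImage::imageData(EBImage::gblur(img, sigma = sigma)))
}

otsuThreshold <- function(m) {
  EBImage::otsu(EBImage::Image(t(m)), range = c(0, 1))
}
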