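#' @useDynLib irisynth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slotNames slot
#' @importFrom stats runif rnorm sd cov
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package route
# through this so that a seed argument fully determines the result.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

stopifNot01 <- function(m, what) {
  if (!all(m %in% c(0, 1)))
    stop(what, " must be binary (values in {0, 1})", call. = FALSE)
}

# Bilinear (images) / nearest-neighbour (masks) resampling. EBImage stores
# images as (x, y) matrices while this package uses (row = y, col = x), so
# transpose around the call.
resizeImage <- function(img, height, width, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(img) == height && ncol(img) == width) return(img)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(t(img), w = width, h = height, filter = filt)
  t(as.matrix(out))
}

resizeMask <- function(mask, height, width) {
  out <- resizeImage(mask, height, width, method = "nearest")
  out <- (out > 0.5) * 1L
  storage.mode(out) <- "integer"
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Write or read a binary mask as an 8-bit PNG
#'
#' Masks are stored with foreground = 255, background = 0, the usual exchange
#' format for segmentation ground truth.
#'
#' @param mask integer/numeric matrix with values in \{0, 1\}.
#' @param path file path of the PNG.
#' @return `writeMaskPNG` returns `path` invisibly; `readMaskPNG` returns an
#'   integer matrix with values in \{0, 1\}.
#' @export
writeMaskPNG <- function(mask, path) {
  stopifNot01(mask, "mask")
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  out <- (m > 0.5) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Write or read a grayscale image as PNG
#'
#' @param img numeric matrix with values in [0, 1].
#' @param path file path.
#' @return `writeImagePNG` returns `path` invisibly; `readImagePNG` a numeric
#'   matrix in [0, 1].
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(clamp01(img), target = path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
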