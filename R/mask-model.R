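#' Sample one eye configuration from the parametric mask family
#'
#' Draws the 11 mask parameters from their configured intervals. Sampling
#' order matters: radii and axis ratios are drawn first, then the iris
#' centre (uniform in the centre box of the frame), then the pupil centre as
#' the iris centre plus isotropic Gaussian jitter, rejected until the pupil
#' circle is geometrically contained in the iris circle, and finally the
#' ellipse-centre offsets, whose bounds ±ratio·irisR/2 depend on the
#' already-sampled ratios and iris radius.
#'
#' @param ranges a \linkS4class{ParameterRanges}.
#' @param seed integer; identical seeds give identical draws. `NULL` uses the
#'   current RNG stream.
#' @return a validated \linkS4class{MaskParameters}.
#' @examples
#' p <- sampleParameters(defaultParameterRanges(), seed = 7)
#' identical(paramsToVector(p),
#'           paramsToVector(sampleParameters(defaultParameterRanges(), seed = 7)))
#' @export
sampleParameters <- function(ranges, seed = NULL) {
  stopifnot(is(ranges, "ParameterRanges"))
  validObject(ranges)
  if (ranges@pupilR[1] >= ranges@irisR[2])
    stop("ranges admit no valid configuration: min pupilR >= max irisR")
  withSeed(seed, {
    irisR <- runif(1, ranges@irisR[1], ranges@irisR[2])
    pupilHi <- min(ranges@pupilR[2], irisR - 1e-6)
    if (ranges@pupilR[1] >= pupilHi)
      stop("ranges admit no valid configuration: pupilR cannot fit inside irisR")
    pupilR <- runif(1, ranges@pupilR[1], pupilHi)
    W <- ranges@frame[1]; H <- ranges@frame[2]
    irisX <- runif(1, ranges@centerBox[1] * W, ranges@centerBox[2] * W)
    irisY <- runif(1, ranges@centerBox[1] * H, ranges@centerBox[2] * H)
    # pupil centre: rejection-sample jitter until the pupil stays inside the iris
    repeat {
      dx <- rnorm(1, 0, ranges@jitterSd)
      dy <- rnorm(1, 0, ranges@jitterSd)
      if (sqrt(dx^2 + dy^2) + pupilR <= irisR) break
    }
    xRatio <- runif(1, ranges@xRatio[1], ranges@xRatio[2])
    yRatio <- runif(1, ranges@yRatio[1], ranges@yRatio[2])
    degree <- runif(1, ranges@degree[1], ranges@degree[2])
    xOffset <- runif(1, -xRatio * irisR / 2, xRatio * irisR / 2)
    yOffset <- runif(1, -yRatio * irisR / 2, yRatio * irisR / 2)
    maskParameters(pupilX = irisX + dx, pupilY = irisY + dy, pupilR = pupilR,
                   irisX = irisX, irisY = irisY, irisR = irisR,
                   xOffset = xOffset, yOffset = yOffset,
                   xRatio = xRatio, yRatio = yRatio, degree = degree)
  })
}

# pixel-centre coordinate grids for a (height x width) raster, 0-based,
# x = column, y = row
coordGrid <- function(height, width) {
  list(x = matrix(rep(0:(width - 1), each = height), height, width),
       y = matrix(rep(0:(height - 1), times = width), height, width))
}

checkResolution <- function(resolution) {
  if (length(resolution) != 2L || any(resolution < 1))
    stop("resolution must be positive c(height, width)", call. = FALSE)
  as.integer(resolution)
}

#' Rasterize the iris mask (annulus between pupil and limbic boundary)
#'
#' A pixel is foreground iff its centre lies inside the iris circle and
#' outside (or on) the pupil circle — the annulus of visible iris texture.
#' No anti-aliasing: the downstream networks expect hard binary labels.
#' Shapes extending beyond the frame are clipped.
#'
#' @param params a \linkS4class{MaskParameters}.
#' @param resolution raster size `c(height, width)`; defaults to the usual
#'   capture frame 480x640.
#' @param clipToPeriocular if `TRUE`, intersect the annulus with the eyelid
#'   ellipse so the mask covers only iris texture actually visible through
#'   the aperture.
#' @return integer matrix in \{0, 1\}.
#' @examples
#' p <- maskParameters(320, 240, 40, 320, 240, 100)
#' sum(rasterizeIrisMask(p)) / (pi * (100^2 - 40^2))  # close to 1
#' @export
rasterizeIrisMask <- function(params, resolution = c(480, 640),
                              clipToPeriocular = FALSE) {
  stopifnot(is(params, "MaskParameters"))
  validObject(params)
  res <- checkResolution(resolution)
  g <- coordGrid(res[1], res[2])
  inIris <- (g$x - params@irisX)^2 + (g$y - params@irisY)^2 <= params@irisR^2
  inPupil <- (g$x - params@pupilX)^2 + (g$y - params@pupilY)^2 < params@pupilR^2
  m <- inIris & !inPupil
  if (clipToPeriocular)
    m <- m & (rasterizePeriocularMask(params, res) == 1L)
  out <- m * 1L
  storage.mode(out) <- "integer"
  out
}

#' Rasterize the periocular mask (rotated eyelid ellipse)
#'
#' A pixel is foreground iff its centre lies inside the ellipse centred at
#' the iris centre plus `(xOffset, yOffset)`, with semi-axes
#' `xRatio * irisR` and `yRatio * irisR`, rotated by `degree`
#' counter-clockwise from the +x axis.
#'
#' @inheritParams rasterizeIrisMask
#' @return integer matrix in \{0, 1\}.
#' @export
rasterizePeriocularMask <- function(params, resolution = c(480, 640)) {
  stopifnot(is(params, "MaskParameters"))
  validObject(params)
  res <- checkResolution(resolution)
  g <- coordGrid(res[1], res[2])
  cx <- params@irisX + params@xOffset
  cy <- params@irisY + params@yOffset
  a <- params@xRatio * params@irisR
  b <- params@yRatio * params@irisR
  th <- params@degree * pi / 180
  u <- cos(th) * (g$x - cx) + sin(th) * (g$y - cy)
  v <- -sin(th) * (g$x - cx) + cos(th) * (g$y - cy)
  out <- ((u / a)^2 + (v / b)^2 <= 1) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Bundle both masks at the network resolution
#'
#' Rasterises at the native frame implied by `frame` and applies the same
#' geometric normalisation the images receive (nearest-neighbour resize to
#' `resolution`, then re-binarisation), so masks and images stay aligned.
#'
#' @inheritParams rasterizeIrisMask
#' @param resolution output size `c(height, width)`, default 256x256.
#' @param frame native raster `c(height, width)` before normalisation;
#'   defaults to `resolution` (direct rasterisation).
#' @return a \linkS4class{ConditionPair}.
#' @export
makeConditionPair <- function(params, resolution = c(256, 256),
                              frame = resolution, clipToPeriocular = FALSE) {
  res <- checkResolution(resolution)
  frm <- checkResolution(frame)
  im <- rasterizeIrisMask(params, frm, clipToPeriocular = clipToPeriocular)
  pm <- rasterizePeriocularMask(params, frm)
  if (!identical(frm, res)) {
    im <- resizeMask(im, res[1], res[2])
    pm <- resizeMask(pm, res[1], res[2])
  }
  conditionPair(im, pm)
}

#' Summary statistics of a set of mask parameter draws
#'
#' Per-parameter average, standard deviation, minimum and maximum — the
#' summary used to calibrate sampling intervals from annotated data.
#'
#' @param annotatedParams a list of \linkS4class{MaskParameters} (or a
#'   matrix/data.frame with the 11 canonical columns).
#' @return a data.frame with rows = the 11 parameters and columns
#'   `average`, `sd`, `min`, `max`.
#' @export
fitParameterStatistics <- function(annotatedParams) {
  if (is.list(annotatedParams) && !is.data.frame(annotatedParams)) {
    if (length(annotatedParams) == 0L) stop("empty parameter list")
    m <- t(vapply(annotatedParams, paramsToVector,
                  numeric(length(maskParameterNames()))))
  } else {
    m <- as.matrix(as.data.frame(annotatedParams)[, maskParameterNames()])
    if (nrow(m) == 0L) stop("empty parameter list")
  }
  data.frame(
    parameter = maskParameterNames(),
    average = apply(m, 2, mean),
    sd = if (nrow(m) > 1L) apply(m, 2, sd) else rep(0, ncol(m)),
    min = apply(m, 2, min),
    max = apply(m, 2, max),
    row.names = NULL
  )
}

#' Serialize mask parameter sets to CSV
#'
#' One row per sample with the 11 canonical column names.
#'
#' @param paramsList list of \linkS4class{MaskParameters}.
#' @param path CSV file path.
#' @return `writeParametersCSV` returns `path` invisibly;
#'   `readParametersCSV` a list of \linkS4class{MaskParameters}.
#' @export
writeParametersCSV <- function(paramsList, path) {
  m <- as.data.frame(t(vapply(paramsList, paramsToVector,
                              numeric(length(maskParameterNames())))))
  names(m) <- maskParameterNames()
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeParametersCSV
#' @export
readParametersCSV <- function(path) {
  m <- read.csv(path)
  lapply(seq_len(nrow(m)), function(i) vectorToParams(unlist(m[i, ])))
}
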