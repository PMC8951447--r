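#' MaskParameters: one eye-shape configuration
#'
#' Eleven parameters describe one eye: a pupil circle (centre, radius), an
#' iris circle (centre, radius), and the elliptical eyelid aperture
#' (periocular region) expressed relative to the iris — centre displacement
#' `(xOffset, yOffset)` from the iris centre, semi-major axis
#' `xRatio * irisR`, semi-minor axis `yRatio * irisR`, rotated by `degree`
#' (counter-clockwise from the +x axis). Coordinates are 0-based pixels,
#' x = column, y = row, origin at the top-left of the capture frame.
#'
#' Validity requires `pupilR < irisR`, geometric containment of the pupil
#' circle inside the iris circle, and positive axis ratios.
#'
#' @slot pupilX,pupilY,pupilR pupil centre and radius (pixels).
#' @slot irisX,irisY,irisR iris centre and radius (pixels).
#' @slot xOffset,yOffset ellipse-centre displacement from the iris centre.
#' @slot xRatio,yRatio semi-axis lengths as multiples of `irisR`.
#' @slot degree ellipse rotation in degrees.
#' @export
setClass("MaskParameters",
  representation(
    pupilX = "numeric", pupilY = "numeric", pupilR = "numeric",
    irisX = "numeric", irisY = "numeric", irisR = "numeric",
    xOffset = "numeric", yOffset = "numeric",
    xRatio = "numeric", yRatio = "numeric", degree = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    for (nm in maskParameterNames())
      if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
        msg <- c(msg, paste0(nm, " must be a single finite number"))
    if (length(msg)) return(msg)
    if (object@pupilR <= 0) msg <- c(msg, "pupilR must be positive")
    if (object@irisR <= 0) msg <- c(msg, "irisR must be positive")
    if (object@pupilR >= object@irisR)
      msg <- c(msg, "pupilR must be smaller than irisR")
    d <- sqrt((object@pupilX - object@irisX)^2 + (object@pupilY - object@irisY)^2)
    if (d + object@pupilR > object@irisR + 1e-9)
      msg <- c(msg, "pupil circle must lie inside the iris circle")
    if (object@xRatio <= 0 || object@yRatio <= 0)
      msg <- c(msg, "xRatio and yRatio must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname MaskParameters-class
#' @return character vector of the 11 parameter names in canonical order.
#' @export
maskParameterNames <- function() {
  c("pupilX", "pupilY", "pupilR", "irisX", "irisY", "irisR",
    "xOffset", "yOffset", "xRatio", "yRatio", "degree")
}

#' Construct a MaskParameters object
#'
#' @param pupilX,pupilY,pupilR,irisX,irisY,irisR,xOffset,yOffset,xRatio,yRatio,degree
#'   see \linkS4class{MaskParameters}.
#' @return a validated \linkS4class{MaskParameters} object.
#' @examples
#' maskParameters(pupilX = 320, pupilY = 240, pupilR = 40,
#'                irisX = 320, irisY = 240, irisR = 100,
#'                xOffset = 0, yOffset = 0, xRatio = 1.8, yRatio = 0.8,
#'                degree = 0)
#' @export
maskParameters <- function(pupilX, pupilY, pupilR, irisX, irisY, irisR,
                           xOffset = 0, yOffset = 0,
                           xRatio = 1.8, yRatio = 0.8, degree = 0) {
  new("MaskParameters",
      pupilX = as.numeric(pupilX), pupilY = as.numeric(pupilY),
      pupilR = as.numeric(pupilR),
      irisX = as.numeric(irisX), irisY = as.numeric(irisY),
      irisR = as.numeric(irisR),
      xOffset = as.numeric(xOffset), yOffset = as.numeric(yOffset),
      xRatio = as.numeric(xRatio), yRatio = as.numeric(yRatio),
      degree = as.numeric(degree))
}

setMethod("show", "MaskParameters", function(object) {
  v <- vapply(maskParameterNames(), function(nm) slot(object, nm), numeric(1))
  cat("MaskParameters\n")
  cat("  pupil : centre (", v["pupilX"], ",", v["pupilY"], "), r =", v["pupilR"], "\n")
  cat("  iris  : centre (", v["irisX"], ",", v["irisY"], "), r =", v["irisR"], "\n")
  cat("  eyelid: offset (", v["xOffset"], ",", v["yOffset"], "), axes ",
      v["xRatio"], "R x ", v["yRatio"], "R, rot ", v["degree"], "deg\n", sep = "")
})

#' Coerce MaskParameters to/from a named numeric vector
#'
#' @param params a \linkS4class{MaskParameters} object.
#' @return `paramsToVector`: named numeric vector in canonical order;
#'   `vectorToParams`: a \linkS4class{MaskParameters}.
#' @export
paramsToVector <- function(params) {
  stopifnot(is(params, "MaskParameters"))
  vapply(maskParameterNames(), function(nm) slot(params, nm), numeric(1))
}

#' @rdname paramsToVector
#' @param x named numeric vector with the 11 canonical names.
#' @export
vectorToParams <- function(x) {
  nms <- maskParameterNames()
  stopifnot(all(nms %in% names(x)))
  do.call(maskParameters, as.list(x[nms]))
}

#' ParameterRanges: sampling intervals for the mask family
#'
#' Closed intervals for each sampled quantity. Offsets are not stored as
#' fixed intervals because their bounds depend on the sampled
#' `xRatio`/`yRatio`/`irisR` (half-axis bounds); the frame and `centerBox`
#' control where iris centres fall.
#'
#' @slot frame numeric length-2, capture frame (width, height) in pixels.
#' @slot pupilR,irisR,xRatio,yRatio,degree numeric length-2 closed intervals.
#' @slot centerBox numeric length-2 fractions (lo, hi) of the frame within
#'   which iris centres are drawn uniformly.
#' @slot jitterSd numeric, isotropic pupil-centre jitter (pixels) about the
#'   iris centre, resampled until containment holds.
#' @export
setClass("ParameterRanges",
  representation(frame = "numeric", pupilR = "numeric", irisR = "numeric",
                 xRatio = "numeric", yRatio = "numeric", degree = "numeric",
                 centerBox = "numeric", jitterSd = "numeric"),
  validity = function(object) {
    msg <- character()
    iv <- function(x, nm) {
      if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
        paste0(nm, " must be a finite interval c(lo, hi) with lo <= hi")
      else character()
    }
    msg <- c(msg, iv(object@pupilR, "pupilR"), iv(object@irisR, "irisR"),
             iv(object@xRatio, "xRatio"), iv(object@yRatio, "yRatio"),
             iv(object@degree, "degree"), iv(object@centerBox, "centerBox"))
    if (length(object@frame) != 2L || any(object@frame <= 0))
      msg <- c(msg, "frame must be positive (width, height)")
    if (length(object@jitterSd) != 1L || object@jitterSd < 0)
      msg <- c(msg, "jitterSd must be a single non-negative number")
    if (all(!nzchar(msg)) || !length(msg)) TRUE else msg[nzchar(msg)]
  }
)

#' Default sampling ranges for the 11-parameter mask family
#'
#' Radii pupilR in [20, 60] and irisR in [70, 120] pixels; axis ratios
#' xRatio in [1.3, 2.5] and yRatio in [0.4, 1.1]; rotation in [-15, 15]
#' degrees; offsets bounded by half the corresponding semi-axis
#' (±ratio·irisR/2). Centres are drawn uniformly over the middle
#' 60 percent of a 640x480 frame so shapes stay mostly in frame.
#'
#' @param frame capture frame (width, height), default `c(640, 480)`.
#' @param pupilR,irisR,xRatio,yRatio,degree closed sampling intervals.
#' @param centerBox fractions of the frame bounding iris centres.
#' @param jitterSd pupil-centre jitter sd in pixels.
#' @return a \linkS4class{ParameterRanges} object.
#' @examples
#' r <- defaultParameterRanges()
#' sampleParameters(r, seed = 1)
#' @export
defaultParameterRanges <- function(frame = c(640, 480),
                                   pupilR = c(20, 60), irisR = c(70, 120),
                                   xRatio = c(1.3, 2.5), yRatio = c(0.4, 1.1),
                                   degree = c(-15, 15),
                                   centerBox = c(0.2, 0.8), jitterSd = 3) {
  new("ParameterRanges", frame = as.numeric(frame),
      pupilR = as.numeric(pupilR), irisR = as.numeric(irisR),
      xRatio = as.numeric(xRatio), yRatio = as.numeric(yRatio),
      degree = as.numeric(degree), centerBox = as.numeric(centerBox),
      jitterSd = as.numeric(jitterSd))
}

#' Scale sampling ranges to a smaller frame
#'
#' Rescales all pixel-valued intervals (radii, frame, jitter) by the frame
#' ratio so the same anatomy family can be sampled at reduced resolution,
#' e.g. for quick end-to-end runs. Dimensionless ratios and the rotation
#' range are untouched.
#'
#' @param ranges a \linkS4class{ParameterRanges}.
#' @param width,height the target frame in pixels.
#' @return a rescaled \linkS4class{ParameterRanges}.
#' @export
scaleRanges <- function(ranges, width, height) {
  stopifnot(is(ranges, "ParameterRanges"), width > 0, height > 0)
  f <- min(width / ranges@frame[1], height / ranges@frame[2])
  new("ParameterRanges", frame = c(width, height),
      pupilR = pmax(ranges@pupilR * f, 1), irisR = pmax(ranges@irisR * f, 2),
      xRatio = ranges@xRatio, yRatio = ranges@yRatio, degree = ranges@degree,
      centerBox = ranges@centerBox, jitterSd = max(ranges@jitterSd * f, 0.25))
}

setMethod("show", "ParameterRanges", function(object) {
  cat("ParameterRanges (frame ", object@frame[1], "x", object@frame[2], ")\n",
      sep = "")
  cat("  pupilR [", object@pupilR[1], ",", object@pupilR[2], "]  irisR [",
      object@irisR[1], ",", object@irisR[2], "]\n")
  cat("  xRatio [", object@xRatio[1], ",", object@xRatio[2], "]  yRatio [",
      object@yRatio[1], ",", object@yRatio[2], "]  degree [",
      object@degree[1], ",", object@degree[2], "]\n")
})

#' ConditionPair: the two-channel mask condition
#'
#' The iris mask and periocular mask rasterised on a common grid; together
#' they form the two-channel condition image fed to the generation network
#' and the labels for downstream segmentation.
#'
#' @slot irisMask integer matrix in \{0, 1\}.
#' @slot periocularMask integer matrix in \{0, 1\}, same dimensions.
#' @export
setClass("ConditionPair",
  representation(irisMask = "matrix", periocularMask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@irisMask), dim(object@periocularMask)))
      msg <- c(msg, "masks must share dimensions")
    if (!all(object@irisMask %in% c(0L, 1L)))
      msg <- c(msg, "irisMask must be binary")
    if (!all(object@periocularMask %in% c(0L, 1L)))
      msg <- c(msg, "periocularMask must be binary")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname ConditionPair-class
#' @param irisMask,periocularMask binary matrices of equal size.
#' @return a validated \linkS4class{ConditionPair}.
#' @export
conditionPair <- function(irisMask, periocularMask) {
  storage.mode(irisMask) <- "integer"
  storage.mode(periocularMask) <- "integer"
  new("ConditionPair", irisMask = irisMask, periocularMask = periocularMask)
}

#' @rdname ConditionPair-class
#' @param object,pair a \linkS4class{ConditionPair}.
#' @export
irisMask <- function(pair) { stopifnot(is(pair, "ConditionPair")); pair@irisMask }

#' @rdname ConditionPair-class
#' @export
periocularMask <- function(pair) {
  stopifnot(is(pair, "ConditionPair")); pair@periocularMask
}

#' @rdname ConditionPair-class
#' @export
conditionResolution <- function(pair) {
  stopifnot(is(pair, "ConditionPair")); dim(pair@irisMask)
}

setMethod("show", "ConditionPair", function(object) {
  d <- dim(object@irisMask)
  cat("ConditionPair ", d[1], "x", d[2],
      "  iris px: ", sum(object@irisMask),
      "  periocular px: ", sum(object@periocularMask), "\n", sep = "")
})

#' FeatureStatistics: Gaussian summary of an embedded image set
#'
#' The sample mean and covariance of image embeddings, the two moments
#' compared by the Frechet distance.
#'
#' @slot mu numeric mean vector.
#' @slot sigma covariance matrix (symmetric, PSD up to numerical noise).
#' @slot n number of images summarised.
#' @export
setClass("FeatureStatistics",
  representation(mu = "numeric", sigma = "matrix", n = "integer"),
  validity = function(object) {
    msg <- character()
    d <- length(object@mu)
    if (!identical(dim(object@sigma), c(d, d)))
      msg <- c(msg, "sigma must be d x d for d = length(mu)")
    else {
      if (max(abs(object@sigma - t(object@sigma))) > 1e-8)
        msg <- c(msg, "sigma must be symmetric (tolerance 1e-8)")
      ev <- eigen(0.5 * (object@sigma + t(object@sigma)),
                  symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(1, max(abs(ev))))
        msg <- c(msg, "sigma must be positive semi-definite (tolerance 1e-8)")
    }
    if (object@n < 2L) msg <- c(msg, "n must be at least 2")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "FeatureStatistics", function(object) {
  cat("FeatureStatistics: d =", length(object@mu), ", n =", object@n, "\n")
})
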