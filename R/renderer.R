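#' RenderConfig: appearance settings for the procedural eye renderer
#'
#' The renderer fabricates grayscale eye images directly from mask
#' parameters so every downstream stage (adversarial synthesis, segmentation
#' training, evaluation) can run without any external dataset. Four
#' intensity classes mimic a near-infrared capture: a dark pupil disc, a
#' mid-grey textured iris annulus, a bright sclera inside the eyelid
#' aperture, and skin outside it.
#'
#' @slot pupil,iris,sclera,skin base intensities in [0, 1].
#' @slot textureAmp amplitude of the iris texture (0 disables it).
#' @slot textureFreq angular frequency of the radial striation pattern.
#' @slot noiseSd sd of additive Gaussian pixel noise (0 disables it).
#' @slot glasses logical; add two specular glare discs and a frame arc.
#' @export
setClass("RenderConfig",
  representation(pupil = "numeric", iris = "numeric", sclera = "numeric",
                 skin = "numeric", textureAmp = "numeric",
                 textureFreq = "numeric", noiseSd = "numeric",
                 glasses = "logical"),
  validity = function(object) {
    msg <- character()
    for (nm in c("pupil", "iris", "sclera", "skin")) {
      v <- slot(object, nm)
      if (length(v) != 1L || v < 0 || v > 1)
        msg <- c(msg, paste0(nm, " intensity must be in [0, 1]"))
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (object@textureAmp < 0) msg <- c(msg, "textureAmp must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname RenderConfig-class
#' @param pupil,iris,sclera,skin,textureAmp,textureFreq,noiseSd,glasses see
#'   \linkS4class{RenderConfig}.
#' @return a validated \linkS4class{RenderConfig}.
#' @examples
#' cfg <- renderConfig(noiseSd = 0)
#' @export
renderConfig <- function(pupil = 0.05, iris = 0.45, sclera = 0.9, skin = 0.72,
                         textureAmp = 0.12, textureFreq = 12,
                         noiseSd = 0.02, glasses = FALSE) {
  new("RenderConfig", pupil = pupil, iris = iris, sclera = sclera, skin = skin,
      textureAmp = textureAmp, textureFreq = textureFreq,
      noiseSd = noiseSd, glasses = isTRUE(glasses))
}

setMethod("show", "RenderConfig", function(object) {
  cat("RenderConfig  levels p/i/s/k:", object@pupil, object@iris,
      object@sclera, object@skin, " texAmp:", object@textureAmp,
      " noiseSd:", object@noiseSd,
      if (object@glasses) " [glasses]" else "", "\n")
})

# seeded smooth noise field: white Gaussian noise blurred to a correlated
# texture; consumes the current RNG stream
smoothNoise <- function(height, width, sigma = 2) {
  z <- matrix(rnorm(height * width), height, width)
  s <- as.matrix(EBImage::gblur(t(z), sigma = sigma))
  t(s) / max(sd(s), 1e-8)
}

#' Render a toy eye image from mask parameters
#'
#' Composites, back to front: skin everywhere, sclera inside the eyelid
#' ellipse, textured iris annulus, pupil disc. Iris texture is a radial
#' striation sinusoid plus seeded smoothed noise, scaled by `textureAmp`;
#' optional glare (glasses mode) adds two bright discs and a frame arc.
#' With `textureAmp = 0` and `noiseSd = 0` the image is piecewise constant
#' with exactly the four configured levels.
#'
#' @param params a \linkS4class{MaskParameters}.
#' @param config a \linkS4class{RenderConfig}.
#' @param resolution raster `c(height, width)`.
#' @param seed integer; identical seeds give identical images.
#' @return numeric matrix in [0, 1].
#' @examples
#' p <- maskParameters(32, 32, 6, 32, 32, 14)
#' img <- renderEye(p, renderConfig(noiseSd = 0), resolution = c(64, 64),
#'                  seed = 1)
#' range(img)
#' @export
renderEye <- function(params, config = renderConfig(),
                      resolution = c(480, 640), seed = NULL) {
  stopifnot(is(params, "MaskParameters"), is(config, "RenderConfig"))
  validObject(config)
  res <- checkResolution(resolution)
  withSeed(seed, {
    H <- res[1]; W <- res[2]
    peri <- rasterizePeriocularMask(params, res) == 1L
    annulus <- rasterizeIrisMask(params, res) == 1L
    irisVis <- annulus & peri
    pupil <- {
      g <- coordGrid(H, W)
      ((g$x - params@pupilX)^2 + (g$y - params@pupilY)^2 < params@pupilR^2) & peri
    }
    img <- matrix(config@skin, H, W)
    img[peri] <- config@sclera
    if (any(irisVis)) {
      g <- coordGrid(H, W)
      phi <- atan2(g$y - params@irisY, g$x - params@irisX)
      rho <- sqrt((g$x - params@irisX)^2 + (g$y - params@irisY)^2) /
        max(params@irisR, 1e-8)
      tex <- 0.6 * sin(config@textureFreq * phi) +
        0.4 * cos(2 * pi * 3 * rho)
      if (config@textureAmp > 0)
        tex <- tex + smoothNoise(H, W, sigma = max(1, params@irisR / 12))
      tex <- pmax(pmin(tex, 1.5), -1.5)  # keep iris band separated from skin
      img[irisVis] <- config@iris + config@textureAmp * 0.5 * tex[irisVis]
    }
    img[pupil] <- config@pupil
    if (config@glasses) {
      g <- coordGrid(H, W)
      r1 <- max(2, 0.12 * params@irisR); r2 <- max(1.5, 0.08 * params@irisR)
      c1 <- c(params@irisX - 0.5 * params@irisR, params@irisY - 0.5 * params@irisR)
      c2 <- c(params@irisX + 0.4 * params@irisR, params@irisY - 0.3 * params@irisR)
      img[(g$x - c1[1])^2 + (g$y - c1[2])^2 < r1^2] <- 1
      img[(g$x - c2[1])^2 + (g$y - c2[2])^2 < r2^2] <- 1
      rho <- sqrt((g$x - params@irisX)^2 + (g$y - params@irisY)^2)
      arc <- abs(rho - 2.2 * params@irisR) < max(1.5, 0.04 * params@irisR) &
        (g$y < params@irisY)
      img[arc] <- 0.95
    }
    if (config@noiseSd > 0)
      img <- img + matrix(rnorm(H * W, 0, config@noiseSd), H, W)
    clamp01(img)
  })
}

#' Render an aligned image/mask dataset
#'
#' Samples `n` parameter sets, renders each eye, and rasterises its
#' condition pair on the same grid, giving perfectly aligned
#' image/iris-mask/periocular-mask triplets plus a manifest of the
#' generating parameters and per-sample seeds. The iris label is clipped to
#' the eyelid aperture so it marks exactly the visible iris texture.
#'
#' @param n number of samples.
#' @param ranges a \linkS4class{ParameterRanges} (already scaled to
#'   `resolution`'s frame, see [scaleRanges()]).
#' @param config a \linkS4class{RenderConfig}.
#' @param resolution raster `c(height, width)`.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param dir optional directory; when given, images and masks are written
#'   as PNG (`img_####.png`, `iris_####.png`, `peri_####.png`) along with
#'   `manifest.csv`.
#' @return a list with `images` (H x W x n array), `irisMasks`,
#'   `periocularMasks` (integer arrays), `params` (list), and `manifest`
#'   (data.frame: id, seed, 11 parameters).
#' @export
renderDataset <- function(n, ranges, config = renderConfig(),
                          resolution = c(64, 64), seed = 1, dir = NULL) {
  stopifnot(n >= 1)
  res <- checkResolution(resolution)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  imgs <- array(0, c(res[1], res[2], n))
  im <- array(0L, c(res[1], res[2], n))
  pm <- array(0L, c(res[1], res[2], n))
  params <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sampleParameters(ranges, seed = seeds[i])
    params[[i]] <- p
    imgs[, , i] <- renderEye(p, config, res, seed = seeds[i] + 1)
    pair <- makeConditionPair(p, resolution = res, clipToPeriocular = TRUE)
    im[, , i] <- irisMask(pair)
    pm[, , i] <- periocularMask(pair)
  }
  manifest <- cbind(
    data.frame(id = seq_len(n), seed = seeds),
    as.data.frame(t(vapply(params, paramsToVector,
                           numeric(length(maskParameterNames())))))
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      tag <- sprintf("%04d", i)
      writeImagePNG(imgs[, , i], file.path(dir, paste0("img_", tag, ".png")))
      writeMaskPNG(im[, , i], file.path(dir, paste0("iris_", tag, ".png")))
      writeMaskPNG(pm[, , i], file.path(dir, paste0("peri_", tag, ".png")))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = imgs, irisMasks = im, periocularMasks = pm,
       params = params, manifest = manifest)
}
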