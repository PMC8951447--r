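#' Build the mask-conditioned U-Net generator
#'
#' Encoder: `depth` stride-2 4x4 convolutions with instance normalisation
#' and LeakyReLU(0.2); decoder: `depth` stride-2 4x4 transposed convolutions
#' with instance normalisation and ReLU, dropout 0.5 on the first five
#' decoder layers, sigmoid output, and a skip connection at every level.
#' Feature widths double each level up to `maxWidthFactor * baseWidth`.
#' Instance normalisation is skipped on 1x1 maps (the bottleneck), where it
#' is undefined. Weights are Gaussian-initialised (sd `initSd`).
#'
#' @param inChannels input channels (2: iris + periocular mask).
#' @param outChannels output channels (1: grayscale image).
#' @param depth number of encoder levels; an input of size `2^depth` reaches
#'   a 1x1 bottleneck (8 for 256x256, 6 for 64x64).
#' @param baseWidth feature width of the first encoder layer.
#' @param maxWidthFactor cap on width growth.
#' @param dropout dropout probability on early decoder layers.
#' @param dropoutLayers how many leading decoder layers get dropout.
#' @param head output nonlinearity: `"sigmoid"`, `"softmax"` or `"linear"`.
#' @param initSd sd of the Gaussian weight initialisation.
#' @param seed RNG seed for initialisation.
#' @return an object of class `irisGenerator`.
#' @export
generatorNetwork <- function(inChannels = 2, outChannels = 1, depth = 8,
                             baseWidth = 64, maxWidthFactor = 8,
                             dropout = 0.5, dropoutLayers = 5,
                             head = "sigmoid", initSd = 0.02, seed = NULL) {
  stopifnot(depth >= 2, baseWidth >= 1)
  head <- match.arg(head, c("sigmoid", "softmax", "linear"))
  withSeed(seed, {
    encW <- pmin(baseWidth * 2^(seq_len(depth) - 1), baseWidth * maxWidthFactor)
    enc <- vector("list", depth)
    for (l in seq_len(depth)) {
      cin <- if (l == 1L) inChannels else encW[l - 1L]
      enc[[l]] <- convLayer(cin, encW[l], norm = TRUE, initSd = initSd)
    }
    dec <- vector("list", depth)
    for (l in seq_len(depth)) {
      cin <- if (l == 1L) encW[depth] else dec[[l - 1L]]$cout + encW[depth - l + 1L]
      cout <- if (l < depth) encW[depth - l] else outChannels
      dec[[l]] <- tconvLayer(cin, cout, norm = l < depth,
                             dropout = if (l <= dropoutLayers && l < depth) dropout else 0,
                             initSd = initSd)
    }
    structure(list(kind = "unet", depth = depth, inChannels = inChannels,
                   outChannels = outChannels, head = head,
                   enc = enc, dec = dec),
              class = "irisGenerator")
  })
}

#' Build the patch discriminator
#'
#' Five 4x4 stride-2 convolutions on the 3-channel (iris mask, periocular
#' mask, image) stack, instance normalisation + LeakyReLU on the first four,
#' sigmoid patch output on the last. On a 256x256 input the feature maps
#' after the fourth convolution are 16x16 and the patch map is 8x8.
#'
#' @param inChannels input channels (2 condition channels + 1 image).
#' @param baseWidth feature width of the first layer.
#' @param nLayers number of convolutions.
#' @param initSd,seed Gaussian initialisation.
#' @return an object of class `irisDiscriminator`.
#' @export
discriminatorNetwork <- function(inChannels = 3, baseWidth = 64, nLayers = 5,
                                 initSd = 0.02, seed = NULL) {
  stopifnot(nLayers >= 2)
  withSeed(seed, {
    widths <- c(pmin(baseWidth * 2^(seq_len(nLayers - 1) - 1), baseWidth * 8), 1L)
    layers <- vector("list", nLayers)
    for (l in seq_len(nLayers)) {
      cin <- if (l == 1L) inChannels else widths[l - 1L]
      layers[[l]] <- convLayer(cin, widths[l], norm = l < nLayers,
                               initSd = initSd)
    }
    structure(list(kind = "chain", inChannels = inChannels, layers = layers),
              class = "irisDiscriminator")
  })
}

#' @export
print.irisGenerator <- function(x, ...) {
  cat("irisGenerator: U-Net depth", x$depth, ",", x$inChannels, "->",
      x$outChannels, "channels, head", x$head, "\n")
  invisible(x)
}

#' @export
print.irisDiscriminator <- function(x, ...) {
  w <- vapply(x$layers, function(l) l$cout, numeric(1))
  cat("irisDiscriminator:", length(x$layers), "conv layers, widths",
      paste(w, collapse = "/"), "\n")
  invisible(x)
}

conditionToArray <- function(condition) {
  if (is(condition, "ConditionPair")) {
    d <- dim(irisMask(condition))
    a <- array(0, c(d[1], d[2], 2, 1))
    a[, , 1, 1] <- irisMask(condition)
    a[, , 2, 1] <- periocularMask(condition)
    a
  } else as4d(condition)
}

#' Generate an image from a mask condition
#'
#' @param generator an `irisGenerator`.
#' @param condition a \linkS4class{ConditionPair} or an array
#'   `(H, W, 2[, N])`; resolution must be divisible by `2^depth`.
#' @param dropout if `TRUE`, decoder dropout stays active (stochastic
#'   output); default `FALSE` makes the forward pass deterministic.
#' @param seed RNG seed used when `dropout = TRUE`.
#' @return a matrix (single condition) or `(H, W, 1, N)` array of images
#'   with values in (0, 1).
#' @export
generatorForward <- function(generator, condition, dropout = FALSE,
                             seed = NULL) {
  stopifnot(inherits(generator, "irisGenerator"))
  x <- conditionToArray(condition)
  out <- withSeed(seed, unetForward(generator, x, train = dropout))$y
  if (dim(out)[4] == 1L && dim(out)[3] == 1L) out <- out[, , 1, 1] else out
}

#' Score a (condition, image) pair with the patch discriminator
#'
#' @param discriminator an `irisDiscriminator`.
#' @param condition a \linkS4class{ConditionPair} or `(H, W, 2[, N])` array.
#' @param image a matrix or `(H, W, 1[, N])` array, same resolution.
#' @return patch score map in [0, 1] (matrix, or `(h, w, 1, N)` array for a
#'   batch).
#' @export
discriminatorForward <- function(discriminator, condition, image) {
  stopifnot(inherits(discriminator, "irisDiscriminator"))
  x <- conditionToArray(condition)
  y <- as4d(image)
  if (!identical(dim(x)[c(1, 2, 4)], dim(y)[c(1, 2, 4)]))
    stop("condition and image resolutions/batch sizes differ")
  out <- chainForward(discriminator, catChannels(x, y))$y
  if (dim(out)[4] == 1L && dim(out)[3] == 1L) out[, , 1, 1] else out
}

#' Spatial sizes of the discriminator feature maps
#'
#' @param discriminator an `irisDiscriminator`.
#' @param resolution input size `c(height, width)`.
#' @return integer matrix, one row per layer, columns height/width.
#' @examples
#' discriminatorFeatureSizes(discriminatorNetwork(baseWidth = 4),
#'                           c(256, 256))
#' @export
discriminatorFeatureSizes <- function(discriminator, resolution = c(256, 256)) {
  x <- array(0.5, c(resolution[1], resolution[2], discriminator$inChannels, 1))
  fw <- chainForward(discriminator, x)
  m <- do.call(rbind, fw$shapes)
  dimnames(m) <- list(paste0("conv", seq_len(nrow(m))), c("height", "width"))
  m
}

LOG_EPS <- 1e-12

clampLog <- function(p) log(pmin(pmax(p, LOG_EPS), 1))

#' Conditional adversarial objective
#'
#' `mean(log D(x, y)) + mean(log(1 - D(x, G(x))))` over all patch scores:
#' the quantity the discriminator ascends and the generator descends. Zero
#' in the perfect-discriminator limit; `2 log 0.5` when every score is 0.5.
#'
#' @param realScores,fakeScores numeric arrays of discriminator outputs in
#'   [0, 1].
#' @return scalar value of the objective.
#' @examples
#' cganObjective(0.5, 0.5)  # 2 * log(0.5)
#' @export
cganObjective <- function(realScores, fakeScores) {
  if (any(realScores < 0 | realScores > 1) || any(fakeScores < 0 | fakeScores > 1))
    stop("discriminator scores must lie in [0, 1]")
  mean(clampLog(realScores)) + mean(clampLog(1 - fakeScores))
}

#' Mean absolute reconstruction term
#'
#' Per-pixel mean of |y - G(x)|, the L1 regulariser that keeps the
#' generator close to the reference image. The per-pixel mean (rather than
#' an unnormalised sum) keeps the loss scale resolution-independent so the
#' conventional weight lambda = 100 applies at any resolution.
#'
#' @param realImage,generatedImage equal-shape numeric arrays.
#' @return scalar mean absolute deviation.
#' @export
l1Term <- function(realImage, generatedImage) {
  if (!identical(dim(realImage) %||% length(realImage),
                 dim(generatedImage) %||% length(generatedImage)))
    stop("image shapes differ")
  mean(abs(realImage - generatedImage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combined generator loss
#'
#' Adversarial term plus `lambda` times the L1 term. The adversarial part
#' uses the non-saturating form `-mean(log D(x, G(x)))` by default (the
#' standard stabilisation); `nonSaturating = FALSE` gives the minimax form
#' `mean(log(1 - D(x, G(x))))`.
#'
#' @param fakeScores discriminator scores on generated images, in [0, 1].
#' @param realImage,generatedImage equal-shape arrays.
#' @param lambda L1 weight (default 100).
#' @param nonSaturating use the non-saturating adversarial form.
#' @return scalar loss.
#' @export
combinedGeneratorLoss <- function(fakeScores, realImage, generatedImage,
                                  lambda = 100, nonSaturating = TRUE) {
  stopifnot(lambda >= 0)
  if (any(fakeScores < 0 | fakeScores > 1))
    stop("discriminator scores must lie in [0, 1]")
  adv <- if (nonSaturating) -mean(clampLog(fakeScores))
  else mean(clampLog(1 - fakeScores))
  adv + lambda * l1Term(realImage, generatedImage)
}

#' Training configuration for the generation network
#'
#' Defaults follow the adversarial training recipe: Adam with learning rate
#' 1e-4, beta1 = 0.5, beta2 = 0.99, batch size 64, L1 weight lambda = 100,
#' Gaussian weight initialisation.
#'
#' @param lr learning rate.
#' @param beta1,beta2 Adam momentum coefficients.
#' @param batchSize minibatch size.
#' @param iterations number of alternating D/G updates.
#' @param lambda L1 weight.
#' @param nonSaturating generator adversarial form (see
#'   [combinedGeneratorLoss()]).
#' @param baseWidth,discBaseWidth feature widths for generator/discriminator.
#' @param generatorDropout decoder dropout probability for a generator built
#'   by this function (0.5 at reference scale; desk-scale presets use 0 —
#'   see the vignette on capacity scaling).
#' @param initSd Gaussian init sd.
#' @param seed master seed for init, batching and dropout.
#' @return a list of class `ganTrainingConfig`.
#' @export
ganTrainingConfig <- function(lr = 1e-4, beta1 = 0.5, beta2 = 0.99,
                              batchSize = 64, iterations = 200, lambda = 100,
                              nonSaturating = TRUE, baseWidth = 64,
                              discBaseWidth = 64, generatorDropout = 0.5,
                              initSd = 0.02, seed = 1) {
  stopifnot(lr > 0, lambda >= 0, batchSize >= 1, iterations >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, batchSize = batchSize,
                 iterations = iterations, lambda = lambda,
                 nonSaturating = nonSaturating, baseWidth = baseWidth,
                 discBaseWidth = discBaseWidth,
                 generatorDropout = generatorDropout,
                 initSd = initSd, seed = seed),
            class = "ganTrainingConfig")
}

stackConditions <- function(irisMasks, periocularMasks) {
  d <- dim(irisMasks)
  x <- array(0, c(d[1], d[2], 2, d[3]))
  x[, , 1, ] <- irisMasks
  x[, , 2, ] <- periocularMasks
  x
}

#' Train the mask-to-image generation network
#'
#' Alternating updates: the discriminator ascends the conditional
#' adversarial objective on (condition, real) vs (condition, generated)
#' stacks; the generator descends its adversarial term plus
#' `lambda *` L1. Every iteration logs the adversarial objective, the
#' generator adversarial term and the L1 term. The run is fully determined
#' by `config$seed`.
#'
#' @param conditions `(H, W, 2, N)` array of mask pairs (or a list of
#'   \linkS4class{ConditionPair}).
#' @param images `(H, W, N)` array of reference images in [0, 1].
#' @param config a [ganTrainingConfig()].
#' @param generator,discriminator optional pre-built networks (defaults are
#'   built to match the data resolution).
#' @param verbose print progress every 25 iterations.
#' @return list with `generator`, `discriminator`, and `history` (data.frame
#'   iteration / dLoss / gAdv / gL1).
#' @export
trainGenerationModel <- function(conditions, images, config = ganTrainingConfig(),
                                 generator = NULL, discriminator = NULL,
                                 verbose = FALSE) {
  if (is.list(conditions) && !is.array(conditions)) {
    im <- vapply(conditions, irisMask, matrix(0L, nrow(irisMask(conditions[[1]])),
                                              ncol(irisMask(conditions[[1]]))))
    pm <- vapply(conditions, periocularMask, im[, , 1] * 0L)
    conditions <- stackConditions(im, pm)
  }
  if (length(dim(images)) == 3L) {
    d <- dim(images)
    dim(images) <- c(d[1], d[2], 1, d[3])
  }
  d <- dim(conditions)
  N <- d[4]
  if (N < 1) stop("empty dataset")
  if (!identical(dim(images)[c(1, 2, 4)], d[c(1, 2, 4)]))
    stop("conditions and images are inconsistent")
  depth <- ceiling(log2(min(d[1], d[2])))
  if (d[1] %% 2^depth != 0 || d[2] %% 2^depth != 0)
    stop("resolution ", d[1], "x", d[2], " is not divisible by 2^depth")

  withSeed(config$seed, {
    if (is.null(generator))
      generator <- generatorNetwork(inChannels = 2, outChannels = 1,
                                    depth = depth, baseWidth = config$baseWidth,
                                    dropout = config$generatorDropout %||% 0.5,
                                    initSd = config$initSd)
    if (is.null(discriminator))
      discriminator <- discriminatorNetwork(inChannels = 3,
                                            baseWidth = config$discBaseWidth,
                                            nLayers = min(5, depth),
                                            initSd = config$initSd)
    gState <- adamState(generator[c("enc", "dec")])
    dState <- adamState(discriminator["layers"])
    hist <- data.frame(iteration = seq_len(config$iterations),
                       dLoss = NA_real_, gAdv = NA_real_, gL1 = NA_real_)
    B <- min(config$batchSize, N)
    for (it in seq_len(config$iterations)) {
      idx <- sample.int(N, B, replace = N < B)
      x <- conditions[, , , idx, drop = FALSE]
      y <- images[, , , idx, drop = FALSE]
      gFw <- unetForward(generator, x, train = TRUE)
      yh <- gFw$y

      # --- discriminator update (ascend Eq. 1) ---
      dReal <- chainForward(discriminator, catChannels(x, y))
      dFake <- chainForward(discriminator, catChannels(x, yh))
      M <- length(dReal$y)
      gzReal <- (dReal$y - 1) / M      # d/dz of -mean log sigmoid(z)
      gzFake <- dFake$y / M            # d/dz of -mean log(1 - sigmoid(z))
      bReal <- chainBackward(discriminator, dReal$cache, gzLast = gzReal)
      bFake <- chainBackward(discriminator, dFake$cache, gzLast = gzFake)
      dGrads <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b,
                                           gamma = if (!is.null(a$gamma)) a$gamma + b$gamma,
                                           beta = if (!is.null(a$beta)) a$beta + b$beta),
                       bReal$layers, bFake$layers, SIMPLIFY = FALSE)
      eq1 <- cganObjective(dReal$y, dFake$y)

      # --- generator update (against the pre-step discriminator, whose
      # fake-pass cache is reused) ---
      if (config$nonSaturating) {
        gAdv <- -mean(clampLog(dFake$y))
        gzAdv <- (dFake$y - 1) / M
      } else {
        gAdv <- mean(clampLog(1 - dFake$y))
        gzAdv <- -dFake$y / M
      }
      bAdv <- chainBackward(discriminator, dFake$cache, gzLast = gzAdv)
      gImg <- bAdv$gx[, , 3, , drop = FALSE]  # gradient reaching the image channel
      l1 <- mean(abs(yh - y))
      gL1 <- config$lambda * sign(yh - y) / length(yh)
      gOut <- gImg + gL1
      up <- adamStep(discriminator["layers"], list(layers = dGrads), dState,
                     config$lr, config$beta1, config$beta2)
      discriminator$layers <- up$params$layers
      dState <- up$state
      bg <- unetBackward(generator, gFw$cache, gy = gOut)
      upg <- adamStep(generator[c("enc", "dec")], bg[c("enc", "dec")], gState,
                      config$lr, config$beta1, config$beta2)
      generator$enc <- upg$params$enc
      generator$dec <- upg$params$dec
      gState <- upg$state

      hist$dLoss[it] <- eq1
      hist$gAdv[it] <- gAdv
      hist$gL1[it] <- l1
      if (verbose && it %% 25 == 0)
        message(sprintf("iter %d  adv obj %.4f  G adv %.4f  L1 %.4f",
                        it, eq1, gAdv, l1))
    }
    list(generator = generator, discriminator = discriminator, history = hist)
  })
}

#' Synthesize a labelled dataset with a trained generator
#'
#' Samples `n` mask configurations, rasterises each condition pair, and
#' runs the generator on it. The masks that conditioned each image are kept
#' with it — they are its segmentation labels, which is what makes the
#' framework self-supervised.
#'
#' @param generator a trained `irisGenerator`.
#' @param n number of samples.
#' @param ranges a \linkS4class{ParameterRanges} scaled to the target frame.
#' @param resolution output size `c(height, width)` (divisible by
#'   `2^depth`).
#' @param seed master seed.
#' @param clipToPeriocular clip the iris label to the eyelid aperture
#'   (default `TRUE`, matching the renderer's labels).
#' @return list with `images` `(H, W, n)`, `irisMasks`, `periocularMasks`,
#'   `params` and `manifest`, mirroring [renderDataset()].
#' @export
synthesizeDataset <- function(generator, n, ranges, resolution = c(64, 64),
                              seed = 1, clipToPeriocular = TRUE) {
  stopifnot(inherits(generator, "irisGenerator"), n >= 1)
  res <- checkResolution(resolution)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  im <- array(0L, c(res[1], res[2], n))
  pm <- array(0L, c(res[1], res[2], n))
  params <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sampleParameters(ranges, seed = seeds[i])
    params[[i]] <- p
    pair <- makeConditionPair(p, resolution = res,
                              clipToPeriocular = clipToPeriocular)
    im[, , i] <- irisMask(pair)
    pm[, , i] <- periocularMask(pair)
  }
  x <- stackConditions(im, pm)
  imgs <- array(0, c(res[1], res[2], n))
  step <- 32L
  for (s in seq(1L, n, by = step)) {
    e <- min(s + step - 1L, n)
    out <- unetForward(generator, x[, , , s:e, drop = FALSE], train = FALSE)$y
    imgs[, , s:e] <- out[, , 1, ]
  }
  manifest <- cbind(
    data.frame(id = seq_len(n), seed = seeds, origin = "generated"),
    as.data.frame(t(vapply(params, paramsToVector,
                           numeric(length(maskParameterNames())))))
  )
  list(images = imgs, irisMasks = im, periocularMasks = pm,
       params = params, manifest = manifest)
}
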