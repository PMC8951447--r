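#' Augmentation recipe for paired image/mask data
#'
#' Random crop, horizontal flip with probability 0.5, resize to the network
#' resolution. Cropping slightly below the native frame enlarges the
#' apparent iris; the default window is 456x608 out of a 480x640 frame,
#' with 432x576 available as the alternative preset. Crop sizes are stored
#' explicitly as `c(height, width)`.
#'
#' @param flipProb horizontal flip probability.
#' @param cropSize crop window `c(height, width)`; `NULL` means full frame.
#' @param outputSize network input size `c(height, width)`.
#' @return a list of class `augmentationConfig`.
#' @export
augmentationConfig <- function(flipProb = 0.5, cropSize = c(456, 608),
                               outputSize = c(256, 256)) {
  stopifnot(flipProb >= 0, flipProb <= 1)
  structure(list(flipProb = flipProb, cropSize = cropSize,
                 outputSize = outputSize),
            class = "augmentationConfig")
}

#' Apply one random augmentation to an aligned image/mask pair
#'
#' Draws a crop window and a flip decision once and applies the identical
#' geometric transform to the image and both masks, then resizes to the
#' output resolution (bilinear for the image, nearest-neighbour for masks,
#' which are re-binarised). The sampled transform is returned so it can be
#' re-applied exactly with [applyAugmentation()].
#'
#' @param image grayscale matrix.
#' @param irisMask,periocularMask binary matrices aligned with `image`.
#' @param config an [augmentationConfig()].
#' @param seed optional seed for the transform draw.
#' @return list with `image`, `irisMask`, `periocularMask`, `transform`.
#' @export
augmentPair <- function(image, irisMask, periocularMask,
                        config = augmentationConfig(), seed = NULL) {
  d <- dim(image)
  cs <- if (is.null(config$cropSize)) d else config$cropSize
  if (cs[1] > d[1] || cs[2] > d[2])
    stop("crop window ", cs[1], "x", cs[2], " exceeds source ", d[1], "x", d[2])
  tr <- withSeed(seed, list(
    top = sample.int(d[1] - cs[1] + 1L, 1L),
    left = sample.int(d[2] - cs[2] + 1L, 1L),
    height = cs[1], width = cs[2],
    flip = runif(1) < config$flipProb
  ))
  out <- applyAugmentation(image, irisMask, periocularMask, tr,
                           config$outputSize)
  out$transform <- tr
  out
}

#' @rdname augmentPair
#' @param transform a transform record from a previous [augmentPair()]
#'   call.
#' @param outputSize output resolution `c(height, width)`.
#' @export
applyAugmentation <- function(image, irisMask, periocularMask, transform,
                              outputSize = c(256, 256)) {
  rows <- transform$top + seq_len(transform$height) - 1L
  cols <- transform$left + seq_len(transform$width) - 1L
  crop <- function(m) m[rows, cols, drop = FALSE]
  flip <- function(m) if (transform$flip) m[, rev(seq_len(ncol(m))), drop = FALSE] else m
  list(
    image = resizeImage(flip(crop(image)), outputSize[1], outputSize[2],
                        "bilinear"),
    irisMask = resizeMask(flip(crop(irisMask)), outputSize[1], outputSize[2]),
    periocularMask = resizeMask(flip(crop(periocularMask)), outputSize[1],
                                outputSize[2])
  )
}

#' Expand a dataset with augmented copies
#'
#' Appends `copies` augmented variants of every sample (random crop +
#' horizontal flip + resize back, identical transform for image and masks)
#' to the arrays. This is the training-set form of the augmentation recipe;
#' it regularises segmentation training and bridges small appearance gaps
#' between synthesised and reference imagery.
#'
#' @param images `(H, W, N)` array.
#' @param irisMasks,periocularMasks matching binary arrays.
#' @param config an [augmentationConfig()]; its `outputSize` should equal
#'   the input resolution.
#' @param copies augmented copies per sample.
#' @param seed master seed.
#' @return list with expanded `images`, `irisMasks`, `periocularMasks`.
#' @export
augmentDataset <- function(images, irisMasks, periocularMasks,
                           config = augmentationConfig(), copies = 1,
                           seed = 1) {
  d <- dim(images)
  n <- d[3]
  total <- n * (1 + copies)
  ai <- array(0, c(d[1], d[2], total))
  am <- array(0L, c(d[1], d[2], total))
  ap <- array(0L, c(d[1], d[2], total))
  ai[, , seq_len(n)] <- images
  am[, , seq_len(n)] <- irisMasks
  ap[, , seq_len(n)] <- periocularMasks
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n * copies))
  k <- n
  for (cp in seq_len(copies)) {
    for (i in seq_len(n)) {
      k <- k + 1L
      a <- augmentPair(images[, , i], irisMasks[, , i], periocularMasks[, , i],
                       config, seed = seeds[k - n])
      ai[, , k] <- a$image
      am[, , k] <- a$irisMask
      ap[, , k] <- a$periocularMask
    }
  }
  list(images = ai, irisMasks = am, periocularMasks = ap)
}

#' Concatenate real and generated dataset manifests
#'
#' Manifests are data.frames with at least an `image` column (file path or
#' sample id) and an `origin` column in \{"real", "generated"\}; the
#' concatenation preserves origins and is shuffled with `seed`.
#'
#' @param real,generated manifest data.frames.
#' @param seed shuffle seed; `NULL` keeps the concatenation order.
#' @return combined manifest.
#' @export
mixDatasets <- function(real, generated, seed = NULL) {
  if (is.null(real$origin)) real$origin <- "real"
  if (is.null(generated$origin)) generated$origin <- "generated"
  stopifnot(all(real$origin %in% c("real", "generated")),
            all(generated$origin %in% c("real", "generated")))
  if (nrow(generated) == 0L) return(real)
  common <- intersect(names(real), names(generated))
  out <- rbind(real[common], generated[common])
  if (!is.null(out$image) && anyDuplicated(out$image))
    stop("path collision between real and generated manifests")
  if (!is.null(seed))
    out <- withSeed(seed, out[sample.int(nrow(out)), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Experiment configuration for the end-to-end loop
#'
#' Desk-scale defaults: a 64x64 frame, a renderer-backed "real" proxy set,
#' 200 adversarial iterations, and a two-row comparison (real only vs real
#' + generated). All sizes and seeds are explicit so a run is a pure
#' function of this object.
#'
#' @param resolution working resolution `c(height, width)`.
#' @param nReal,nTest,nSynth sample counts for the real-proxy training set,
#'   held-out test set, and generated set.
#' @param compositions character subset of
#'   `c("real", "real+generated", "generated")` — the training-set rows of
#'   the report.
#' @param ganIterations,ganBatch,ganWidth,ganLr adversarial training scale
#'   and rate (the toy-scale rate; see the vignette on scale-dependent
#'   learning rates).
#' @param segEpochs,segBatch,segWidth,segLr segmentation training scale.
#' @param renderConfig a \linkS4class{RenderConfig}.
#' @param ranges a \linkS4class{ParameterRanges} for the native 640x480
#'   frame; it is rescaled to `resolution` internally.
#' @param seed master seed.
#' @return a list of class `experimentConfig`.
#' @export
experimentConfig <- function(resolution = c(64, 64), nReal = 120, nTest = 60,
                             nSynth = 240,
                             compositions = c("real", "real+generated"),
                             ganIterations = 200, ganBatch = 16, ganWidth = 16,
                             ganLr = 1e-3, segEpochs = 10, segBatch = 8,
                             segWidth = 8, segLr = 1e-3,
                             renderConfig = irisynth::renderConfig(),
                             ranges = defaultParameterRanges(), seed = 1) {
  compositions <- match.arg(compositions,
                            c("real", "real+generated", "generated"),
                            several.ok = TRUE)
  structure(list(resolution = resolution, nReal = nReal, nTest = nTest,
                 nSynth = nSynth, compositions = compositions,
                 ganIterations = ganIterations, ganBatch = ganBatch,
                 ganWidth = ganWidth, ganLr = ganLr, segEpochs = segEpochs,
                 segBatch = segBatch, segWidth = segWidth, segLr = segLr,
                 renderConfig = renderConfig, ranges = ranges, seed = seed),
            class = "experimentConfig")
}

evaluateSegmenter <- function(model, images, irisMasks) {
  d <- dim(images)
  cm <- matrix(0, 2, 2)
  step <- 32L
  for (s in seq(1L, d[3], by = step)) {
    e <- min(s + step - 1L, d[3])
    x <- images[, , s:e, drop = FALSE]
    dim(x) <- c(d[1], d[2], 1, e - s + 1L)
    P <- unetForward(model, x, train = FALSE)$y
    for (n in seq_len(e - s + 1L))
      cm <- cm + pixelConfusion(argmaxClasses(P[, , , n]),
                                irisMasks[, , s + n - 1L], 2)
  }
  list(confusion = cm, metrics = segmentationMetrics(cm))
}

#' Run the complete self-supervised loop at configured scale
#'
#' Renders a real-proxy training set and a held-out test set, trains the
#' mask-to-image network on the training set, synthesises a generated set
#' from freshly sampled masks, trains one segmenter per requested
#' training-set composition, and evaluates each on the held-out set. The
#' whole run is hermetic and a deterministic function of the master seed.
#'
#' @param config an [experimentConfig()].
#' @param verbose print stage progress.
#' @return list with `report` (one row per composition, columns
#'   PA/mPA/mIoU/FWIoU), `ganHistory`, `segHistories`, and the trained
#'   `generator`.
#' @export
runExperiment <- function(config = experimentConfig(), verbose = FALSE) {
  res <- checkResolution(config$resolution)
  ranges <- scaleRanges(config$ranges, res[2], res[1])
  say <- function(...) if (verbose) message(...)

  say("[1/5] rendering real-proxy data")
  train <- renderDataset(config$nReal, ranges, config$renderConfig, res,
                         seed = config$seed)
  test <- renderDataset(config$nTest, ranges, config$renderConfig, res,
                        seed = config$seed + 7919)

  say("[2/5] adversarial training")
  gan <- trainGenerationModel(
    stackConditions(train$irisMasks, train$periocularMasks), train$images,
    ganTrainingConfig(lr = config$ganLr, batchSize = config$ganBatch,
                      iterations = config$ganIterations,
                      baseWidth = config$ganWidth, discBaseWidth = 8,
                      nonSaturating = FALSE, generatorDropout = 0,
                      seed = config$seed + 1))

  say("[3/5] synthesizing labelled data")
  synth <- synthesizeDataset(gan$generator, config$nSynth, ranges, res,
                             seed = config$seed + 2)

  bind3 <- function(a, b) {
    d <- dim(a)
    out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
    out[, , seq_len(d[3])] <- a
    out[, , d[3] + seq_len(dim(b)[3])] <- b
    out
  }

  segHistories <- list()
  report <- NULL
  for (comp in config$compositions) {
    say("[4/5] training segmenter on: ", comp)
    if (comp == "real") {
      imgs <- train$images; labs <- train$irisMasks
    } else if (comp == "generated") {
      imgs <- synth$images; labs <- synth$irisMasks
    } else {
      imgs <- bind3(train$images, synth$images)
      labs <- bind3(train$irisMasks, synth$irisMasks)
    }
    # one augmented copy per sample (crop 7/8 frame + flip), the
    # training-set form of the augmentation recipe
    acfg <- augmentationConfig(flipProb = 0.5,
                               cropSize = round(res * 7 / 8),
                               outputSize = res)
    aug <- augmentDataset(imgs, labs, labs, acfg, copies = 1,
                          seed = config$seed + 4)
    fit <- trainSegmentation(aug$images, aug$irisMasks,
                             segConfig(classes = 2, lr = config$segLr,
                                       batchSize = config$segBatch,
                                       epochs = config$segEpochs,
                                       baseWidth = config$segWidth,
                                       seed = config$seed + 3))
    segHistories[[comp]] <- fit$history
    ev <- evaluateSegmenter(fit$model, test$images, test$irisMasks)
    report <- rbind(report,
                    data.frame(trainingSet = comp,
                               n = dim(imgs)[3],
                               PA = ev$metrics["PA"], mPA = ev$metrics["mPA"],
                               mIoU = ev$metrics["mIoU"],
                               FWIoU = ev$metrics["FWIoU"],
                               row.names = NULL))
  }
  say("[5/5] done")
  list(report = report, ganHistory = gan$history,
       segHistories = segHistories, generator = gan$generator)
}
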