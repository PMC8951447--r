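#' Configuration for the segmentation network
#'
#' The segmenter reuses the generator architecture with the input channel
#' set to one (grayscale) and a channel-wise softmax head producing an
#' n-class per-pixel distribution. Training defaults: Adam, learning rate
#' 1e-5, beta1 = 0.5, beta2 = 0.99, batch size 64, 10 epochs, Gaussian
#' initialisation.
#'
#' @param classes number of pixel classes (>= 2); default 2, iris vs
#'   non-iris. Use 3 for background / periocular / iris.
#' @param lr,beta1,beta2,batchSize,epochs optimiser recipe.
#' @param baseWidth feature width of the first encoder layer.
#' @param initSd Gaussian init sd.
#' @param seed master seed for init, shuffling and dropout.
#' @return a list of class `segConfig`.
#' @export
segConfig <- function(classes = 2, lr = 1e-5, beta1 = 0.5, beta2 = 0.99,
                      batchSize = 64, epochs = 10, baseWidth = 64,
                      initSd = 0.02, seed = 1) {
  stopifnot(classes >= 2, lr > 0, epochs >= 1, batchSize >= 1)
  structure(list(classes = as.integer(classes), lr = lr, beta1 = beta1,
                 beta2 = beta2, batchSize = batchSize, epochs = epochs,
                 baseWidth = baseWidth, initSd = initSd, seed = seed),
            class = "segConfig")
}

#' Build the segmentation network
#'
#' The generator architecture with a single input channel and a channel-wise
#' softmax head. Decoder dropout is disabled: it is the generation network's
#' noise source, not part of the segmentation task.
#'
#' @param classes number of output classes.
#' @param depth encoder depth (input size `2^depth` reaches the 1x1
#'   bottleneck).
#' @param baseWidth,initSd,seed see [generatorNetwork()].
#' @return an `irisSegmenter` (a U-Net with softmax head).
#' @export
segNetwork <- function(classes = 2, depth = 8, baseWidth = 64,
                       initSd = 0.02, seed = NULL) {
  net <- generatorNetwork(inChannels = 1, outChannels = classes,
                          depth = depth, baseWidth = baseWidth,
                          dropout = 0, head = "softmax", initSd = initSd,
                          seed = seed)
  class(net) <- c("irisSegmenter", class(net))
  net
}

#' Per-pixel class probabilities for an image
#'
#' @param model an `irisSegmenter`.
#' @param image grayscale matrix or `(H, W, 1[, N])` array; resolution
#'   divisible by `2^depth`.
#' @return `(H, W, classes)` array (or `(H, W, classes, N)` for a batch)
#'   with per-pixel probabilities summing to one.
#' @export
segForward <- function(model, image) {
  stopifnot(inherits(model, "irisSegmenter"))
  x <- as4d(image)
  if (dim(x)[3] != 1L) stop("segmentation input must be single-channel")
  p <- unetForward(model, x, train = FALSE)$y
  if (dim(p)[4] == 1L) p[, , , 1] else p
}

#' Summed per-pixel cross-entropy (FCN loss)
#'
#' `-sum_i sum_j sum_k Q_k(i,j) log P_k(i,j)`: cross-entropy added up over
#' every pixel position, not averaged. Dividing by `w*h` recovers the mean
#' form. For a batch (4-d arrays) the per-image sums are averaged.
#'
#' @param P `(H, W, K[, N])` array of per-pixel class probabilities.
#' @param Q same-shape one-hot label array.
#' @return scalar loss.
#' @examples
#' P <- array(0.5, c(4, 4, 2)); Q <- array(0, c(4, 4, 2)); Q[, , 1] <- 1
#' fcnLoss(P, Q)  # 16 * log(2)
#' @export
fcnLoss <- function(P, Q) {
  if (!identical(dim(P), dim(Q))) stop("P and Q shapes differ")
  ll <- Q * log(pmax(P, LOG_EPS))
  if (length(dim(P)) == 4L) -sum(ll) / dim(P)[4] else -sum(ll)
}

labelsToOneHot <- function(labels, classes) {
  if (length(dim(labels)) == 4L) return(labels)  # already one-hot
  d <- dim(labels)
  if (length(d) == 2L) d <- c(d, 1L)
  dim(labels) <- d
  Q <- array(0, c(d[1], d[2], classes, d[3]))
  for (k in seq_len(classes) - 1L)
    Q[, , k + 1L, ] <- (labels == k) * 1
  Q
}

#' Train the segmentation network
#'
#' Minibatch Adam on the summed cross-entropy loss. Labels may be integer
#' class maps `(H, W, N)` with values in `0..classes-1` or one-hot arrays
#' `(H, W, K, N)`. With validation data, per-epoch validation loss and mIoU
#' are logged.
#'
#' @param images `(H, W, N)` array of grayscale images.
#' @param labels class maps or one-hot labels (see above).
#' @param config a [segConfig()].
#' @param model optional pre-built `irisSegmenter`.
#' @param valImages,valLabels optional held-out set.
#' @param verbose print per-epoch progress.
#' @return list with `model` and `history` (data.frame epoch / loss and,
#'   with validation data, valLoss / valMIoU).
#' @export
trainSegmentation <- function(images, labels, config = segConfig(),
                              model = NULL, valImages = NULL,
                              valLabels = NULL, verbose = FALSE) {
  d <- dim(images)
  if (length(d) != 3L || d[3] < 1) stop("images must be a non-empty (H, W, N) array")
  N <- d[3]
  K <- config$classes
  Q <- labelsToOneHot(labels, K)
  if (!identical(dim(Q), c(d[1], d[2], K, N)))
    stop("labels are inconsistent with images")
  depth <- ceiling(log2(min(d[1], d[2])))
  withSeed(config$seed, {
    if (is.null(model))
      model <- segNetwork(classes = K, depth = depth,
                          baseWidth = config$baseWidth, initSd = config$initSd)
    state <- adamState(model[c("enc", "dec")])
    B <- min(config$batchSize, N)
    hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)
    hasVal <- !is.null(valImages)
    if (hasVal) {
      hist$valLoss <- NA_real_
      hist$valMIoU <- NA_real_
      valQ <- labelsToOneHot(valLabels, K)
    }
    x <- images
    dim(x) <- c(d[1], d[2], 1, N)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      tot <- 0; nb <- 0
      for (s in seq(1L, N, by = B)) {
        idx <- ord[s:min(s + B - 1L, N)]
        xb <- x[, , , idx, drop = FALSE]
        qb <- Q[, , , idx, drop = FALSE]
        fw <- unetForward(model, xb, train = TRUE)
        P <- fw$y
        loss <- -sum(qb * log(pmax(P, LOG_EPS))) / length(idx)
        gz <- (P - qb) / length(idx)   # gradient of summed CE wrt logits
        bg <- unetBackward(model, fw$cache, gzLast = gz)
        up <- adamStep(model[c("enc", "dec")], bg[c("enc", "dec")], state,
                       config$lr, config$beta1, config$beta2)
        model$enc <- up$params$enc
        model$dec <- up$params$dec
        state <- up$state
        tot <- tot + loss; nb <- nb + 1
      }
      hist$loss[ep] <- tot / nb
      if (hasVal) {
        vd <- dim(valImages)
        vx <- valImages
        dim(vx) <- c(vd[1], vd[2], 1, vd[3])
        vP <- unetForward(model, vx, train = FALSE)$y
        hist$valLoss[ep] <- -sum(valQ * log(pmax(vP, LOG_EPS))) / vd[3]
        cm <- matrix(0, K, K)
        for (n in seq_len(vd[3]))
          cm <- cm + pixelConfusion(argmaxClasses(vP[, , , n]),
                                    argmaxClasses(valQ[, , , n]), K)
        hist$valMIoU[ep] <- meanIoU(cm)
      }
      if (verbose)
        message(sprintf("epoch %d  loss %.2f%s", ep, hist$loss[ep],
                        if (hasVal) sprintf("  val mIoU %.3f", hist$valMIoU[ep]) else ""))
    }
    list(model = model, history = hist)
  })
}

# argmax over the class dim of an (H, W, K) probability array;
# ties resolved toward the lower class index
argmaxClasses <- function(p) {
  d <- dim(p)
  m <- matrix(p, d[1] * d[2], d[3])
  cls <- max.col(m, ties.method = "first") - 1L
  matrix(cls, d[1], d[2])
}

#' Predict a binary iris mask
#'
#' Argmax over the per-pixel class distribution, ties broken toward the
#' lower class index. With the default binary class set, class 1 is iris.
#'
#' @param model a trained `irisSegmenter`.
#' @param image grayscale matrix (or batch array).
#' @param irisClass which class index is "iris" (default: the last class).
#' @return integer matrix in \{0, 1\} (or `(H, W, N)` array for a batch).
#' @export
predictMask <- function(model, image, irisClass = NULL) {
  p <- segForward(model, image)
  if (is.null(irisClass)) irisClass <- model$outChannels - 1L
  if (length(dim(p)) == 3L) {
    out <- (argmaxClasses(p) == irisClass) * 1L
    storage.mode(out) <- "integer"
    out
  } else {
    d <- dim(p)
    out <- array(0L, c(d[1], d[2], d[4]))
    for (n in seq_len(d[4]))
      out[, , n] <- (argmaxClasses(p[, , , n]) == irisClass) * 1L
    out
  }
}
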