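#' Per-pixel confusion matrix
#'
#' Entry (i, j) counts pixels of true class i predicted as class j (0-based
#' class labels, 1-based matrix indices).
#'
#' @param pred,true equal-shape integer label maps with values in
#'   `0..k-1`.
#' @param k number of classes.
#' @return k x k integer matrix.
#' @export
pixelConfusion <- function(pred, true, k) {
  if (length(pred) != length(true)) stop("pred and true shapes differ")
  p <- as.integer(pred); t <- as.integer(true)
  if (any(p < 0L | p >= k) || any(t < 0L | t >= k))
    stop("labels must lie in [0, k)")
  m <- matrix(tabulate(t * k + p + 1L, nbins = k * k), k, k, byrow = TRUE)
  m
}

checkCM <- function(cm) {
  if (sum(cm) == 0) stop("confusion matrix has zero total count")
  if (any(cm < 0)) stop("confusion matrix has negative entries")
  invisible(cm)
}

#' Segmentation metrics from a confusion matrix
#'
#' `pixelAccuracy`: fraction of correctly labelled pixels (trace / total).
#' `meanPixelAccuracy`: per-class recall averaged over the classes present
#' in the ground truth (absent classes have an undefined ratio and are
#' excluded). `meanIoU`: intersection-over-union
#' `p_ii / (sum_j p_ij + sum_j p_ji - p_ii)` averaged the same way.
#' `fwIoU`: IoU weighted by each class's ground-truth frequency, which
#' compensates class imbalance. All four lie in [0, 1] and equal 1 exactly
#' when the confusion matrix is diagonal.
#'
#' @param cm confusion matrix from [pixelConfusion()].
#' @return scalar in [0, 1].
#' @examples
#' cm <- pixelConfusion(c(0, 0, 1, 1), c(0, 0, 0, 1), k = 2)
#' pixelAccuracy(cm)
#' meanIoU(cm)
#' @export
pixelAccuracy <- function(cm) {
  checkCM(cm)
  sum(diag(cm)) / sum(cm)
}

#' @rdname pixelAccuracy
#' @export
meanPixelAccuracy <- function(cm) {
  checkCM(cm)
  rs <- rowSums(cm)
  present <- rs > 0
  mean(diag(cm)[present] / rs[present])
}

#' @rdname pixelAccuracy
#' @export
meanIoU <- function(cm) {
  checkCM(cm)
  rs <- rowSums(cm); cs <- colSums(cm); di <- diag(cm)
  present <- rs > 0
  union <- rs + cs - di
  mean(di[present] / union[present])
}

#' @rdname pixelAccuracy
#' @export
fwIoU <- function(cm) {
  checkCM(cm)
  rs <- rowSums(cm); cs <- colSums(cm); di <- diag(cm)
  union <- rs + cs - di
  iou <- ifelse(union > 0, di / union, 0)
  sum(rs / sum(cm) * iou)
}

#' All four segmentation metrics at once
#'
#' @param cm confusion matrix.
#' @return named numeric vector PA / mPA / mIoU / FWIoU.
#' @export
segmentationMetrics <- function(cm) {
  c(PA = pixelAccuracy(cm), mPA = meanPixelAccuracy(cm),
    mIoU = meanIoU(cm), FWIoU = fwIoU(cm))
}

#' Deterministic pixel-moment embedding
#'
#' A light image embedding for Frechet-distance comparisons when the
#' canonical pretrained 2048-d embedding is unavailable or too heavy:
#' the image bilinearly downsampled to `size x size`, plus its global mean
#' and standard deviation. Deterministic, so desk-scale distance tests are
#' reproducible without downloading weights.
#'
#' @param size downsampling side length (embedding dimension `size^2 + 2`).
#' @return a function mapping a grayscale matrix to a numeric vector.
#' @export
pixelMomentEmbedder <- function(size = 8) {
  force(size)
  function(img) {
    img <- as.matrix(img)
    c(as.vector(resizeImage(img, size, size, "bilinear")),
      mean(img), sd(as.vector(img)))
  }
}

#' Gaussian summary of an embedded image set
#'
#' Embeds every image and returns the sample mean and covariance of the
#' embeddings — the sufficient statistics compared by the Frechet
#' distance.
#'
#' @param images `(H, W, N)` array or list of grayscale matrices, N >= 2.
#' @param embedder function mapping an image matrix to a d-vector
#'   (default [pixelMomentEmbedder()]).
#' @return a \linkS4class{FeatureStatistics}.
#' @export
featureStatistics <- function(images, embedder = pixelMomentEmbedder()) {
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  if (n < 2L) stop("need at least 2 images to estimate covariance")
  d <- length(embedder(images[[1]]))
  E <- vapply(images, function(im) as.numeric(embedder(im)), numeric(d))
  E <- if (d == 1L) matrix(E, ncol = 1L) else t(E)
  sig <- cov(E)
  sig <- 0.5 * (sig + t(sig))
  new("FeatureStatistics", mu = colMeans(E), sigma = sig, n = as.integer(n))
}

# principal square root of a symmetric PSD matrix via eigendecomposition,
# small negative eigenvalues clipped to zero
symSqrt <- function(S) {
  e <- eigen(0.5 * (S + t(S)), symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two Gaussian image-feature summaries
#'
#' `||mu_r - mu_g||^2 + Tr(Sigma_r + Sigma_g - 2 (Sigma_r Sigma_g)^{1/2})`.
#' Zero for identical statistics; lower means the two image sets are more
#' alike. The matrix square root is taken through the symmetrised product
#' `A Sigma_g A` with `A = Sigma_r^{1/2}`; numerically negative
#' eigenvalues are clipped to zero so the result is never negative beyond
#' round-off.
#'
#' @param statsReal,statsGen \linkS4class{FeatureStatistics} of equal
#'   dimension.
#' @return non-negative scalar.
#' @examples
#' s <- new("FeatureStatistics", mu = c(0, 0), sigma = diag(2), n = 10L)
#' fidScore(s, s)  # 0
#' @export
fidScore <- function(statsReal, statsGen) {
  stopifnot(is(statsReal, "FeatureStatistics"), is(statsGen, "FeatureStatistics"))
  if (length(statsReal@mu) != length(statsGen@mu))
    stop("embedding dimensions differ")
  Sr <- statsReal@sigma; Sg <- statsGen@sigma
  A <- symSqrt(Sr)
  covMean <- symSqrt(A %*% Sg %*% A)
  val <- sum((statsReal@mu - statsGen@mu)^2) +
    sum(diag(Sr)) + sum(diag(Sg)) - 2 * sum(diag(covMean))
  max(val, 0)
}

#' Evaluate predicted masks against ground truth
#'
#' Aggregates one confusion matrix over a whole set and reports the four
#' segmentation metrics. Inputs may be arrays `(H, W, N)` or directories
#' of {0, 255} PNG masks with matching file names.
#'
#' @param pred,truth binary mask arrays, lists of matrices, or directory
#'   paths.
#' @param k number of classes (binary masks: 2).
#' @return list with `confusion` and `metrics` (named vector
#'   PA/mPA/mIoU/FWIoU).
#' @export
evaluateMasks <- function(pred, truth, k = 2) {
  loadSet <- function(x) {
    if (is.character(x) && length(x) == 1L && dir.exists(x)) {
      f <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
      lapply(f, readMaskPNG)
    } else if (is.array(x) && length(dim(x)) == 3L) {
      lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    } else if (is.matrix(x)) list(x) else as.list(x)
  }
  P <- loadSet(pred); G <- loadSet(truth)
  if (length(P) != length(G)) stop("prediction and truth counts differ")
  cm <- matrix(0, k, k)
  for (i in seq_along(P)) cm <- cm + pixelConfusion(P[[i]], G[[i]], k)
  list(confusion = cm, metrics = segmentationMetrics(cm))
}
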