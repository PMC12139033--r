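# Trainable convolutional spot segmentation.
#
# A compact two-layer fully convolutional pixel classifier: a learned bank
# of kernels, ReLU, and a 1x1 logistic output giving a per-pixel
# spot-probability map.  Written directly in R (matrix algebra via im2col
# for training, FFT convolution for full-frame prediction); small enough to
# train on a single CPU in well under a minute on simulator patches.

# im2col with zero padding: rows = pixels (column-major), cols = k^2 offsets
# in column-major (dy, dx) order; X %*% kernelVector == correlation.
im2col <- function(img, k) {
  n <- nrow(img); m <- ncol(img); h <- (k - 1L) %/% 2L
  P <- matrix(0, n + 2L * h, m + 2L * h)
  P[(1L + h):(n + h), (1L + h):(m + h)] <- img
  X <- matrix(0, n * m, k * k)
  idx <- 1L
  for (dx in -h:h) for (dy in -h:h) {
    X[, idx] <- as.vector(P[(1L + h + dy):(n + h + dy),
                            (1L + h + dx):(m + h + dx)])
    idx <- idx + 1L
  }
  X
}

# robust per-image normalization used for all model inputs
netNormalize <- function(img) {
  s <- stats::mad(img)
  if (s == 0) s <- max(stats::sd(img), 1)
  (img - stats::median(img)) / s
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# per-pixel spot-probability target: unit-peak Gaussian blobs at the truth
netTarget <- function(px, truth, psfSigma) {
  em <- emitters(truth)
  t <- renderSpots(px, em$x, em$y,
                   rep(2 * pi * psfSigma^2, nrow(em)), psfSigma)
  pmin(t, 1)
}

#' Train the spot-segmentation model on simulated scenes
#'
#' Trains the two-layer convolutional pixel classifier of
#' [SpotNetModel-class] on ground-truthed simulator output.  The training
#' target is a map of unit-peak Gaussian blobs (width `psfSigma`) centred on
#' the true emitter positions; the loss is positive-weighted binary
#' cross-entropy, minimized by Adam with one scene per step.  Inputs are
#' normalized per image by (median, MAD).  Training is deterministic for a
#' fixed seed (single-threaded).
#'
#' @param scenes list of scenes as returned by [simulateScene()] (at least
#'   50, each a list with `micrograph` and `groundTruth`).
#' @param psfSigma PSF width of the scenes, px.
#' @param epochs training epochs.
#' @param nFilters number of first-layer kernels.
#' @param kernelSize kernel side, px (odd).
#' @param lr Adam learning rate.
#' @param posWeight extra loss weight on spot pixels (they are sparse).
#' @param seed integer seed for weight initialization and scene order.
#' @return A trained [SpotNetModel-class].
#' @seealso [detectNet()], [saveSpotNet()]
#' @export
trainSpotNet <- function(scenes, psfSigma = 1.3, epochs = 30L,
    nFilters = 8L, kernelSize = 9L, lr = 0.01, posWeight = 5, seed = 1L) {
  if (length(scenes) < 50L)
    stop("at least 50 training scenes with ground truth are required")
  if (kernelSize %% 2L == 0L) stop("kernelSize must be odd")
  k2 <- kernelSize^2

  prep <- lapply(scenes, function(s) {
    img <- netNormalize(pixelData(s$micrograph))
    list(X = im2col(img, kernelSize),
         t = as.vector(netTarget(nrow(img), s$groundTruth, psfSigma)))
  })

  withSeed(seed, {
    W1 <- matrix(stats::rnorm(k2 * nFilters, sd = 1 / sqrt(k2)), k2, nFilters)
    b1 <- rep(0, nFilters)
    w2 <- stats::rnorm(nFilters, sd = 0.3)
    b2 <- -3
    mom <- list(); vel <- list()
    for (nm in c("W1", "b1", "w2", "b2")) {
      mom[[nm]] <- get(nm) * 0; vel[[nm]] <- get(nm) * 0
    }
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    lossHistory <- numeric(epochs)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(prep))
      epLoss <- 0
      for (si in ord) {
        X <- prep[[si]]$X; t <- prep[[si]]$t
        Z1 <- sweep(X %*% W1, 2L, b1, "+")
        A1 <- pmax(Z1, 0)
        p <- sigmoid(drop(A1 %*% w2) + b2)
        u <- 1 + posWeight * t
        su <- sum(u)
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        epLoss <- epLoss - sum(u * (t * log(pc) + (1 - t) * log(1 - pc))) / su

        dz2 <- u * (p - t) / su
        g <- list(
          w2 = drop(crossprod(A1, dz2)),
          b2 = sum(dz2))
        dA1 <- outer(dz2, w2)
        dZ1 <- dA1 * (Z1 > 0)
        g$W1 <- crossprod(X, dZ1)
        g$b1 <- colSums(dZ1)

        step <- step + 1L
        for (nm in names(g)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- mom[[nm]] / (1 - beta1^step)
          vhat <- vel[[nm]] / (1 - beta2^step)
          assign(nm, get(nm) - lr * mhat / (sqrt(vhat) + eps))
        }
      }
      lossHistory[ep] <- epLoss / length(prep)
    }
    if (!all(is.finite(lossHistory)))
      stop("training loss diverged; check input normalization")

    new("SpotNetModel", W1 = W1, b1 = b1, w2 = w2, b2 = b2,
        kernelSize = as.integer(kernelSize), psfSigma = psfSigma,
        loss = lossHistory)
  })
}

#' Per-pixel spot-probability map from a trained model
#'
#' @param model a [SpotNetModel-class].
#' @param micrograph a [Micrograph-class] or numeric matrix.
#' @return Numeric matrix of spot probabilities in `[0, 1]`.
#' @export
predictSpotMap <- function(model, micrograph) {
  img <- if (is(micrograph, "Micrograph")) micrograph@pixels else micrograph
  imgN <- netNormalize(img)
  k <- model@kernelSize
  z2 <- matrix(model@b2, nrow(img), ncol(img))
  for (cf in seq_len(ncol(model@W1))) {
    K <- matrix(model@W1[, cf], k, k)
    # filter2 convolves with the flipped kernel; flip to get correlation,
    # zero boundary matching the training-time im2col padding
    r <- EBImage::filter2(imgN, K[k:1, k:1, drop = FALSE], boundary = 0)
    z2 <- z2 + model@w2[cf] * pmax(r + model@b1[cf], 0)
  }
  sigmoid(z2)
}

#' Localize spots with the trained segmentation model
#'
#' Thresholds the probability map from [predictSpotMap()], labels connected
#' components, and reports the probability-weighted centroid of each
#' component; the score is the component's peak probability.
#'
#' @param model a trained [SpotNetModel-class].
#' @param micrograph a [Micrograph-class] or numeric matrix.
#' @param probThreshold probability threshold for the segmentation mask.
#' @return A data.frame with columns `x`, `y` (0-based subpixel) and `score`.
#' @export
detectNet <- function(model, micrograph, probThreshold = 0.5) {
  p <- predictSpotMap(model, micrograph)
  mask <- p > probThreshold
  if (!any(mask))
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  wts <- p[idx]
  rows <- (idx - 1L) %% nrow(p) + 1L
  cols <- (idx - 1L) %/% nrow(p) + 1L
  sw <- tapply(wts, comp, sum)
  x <- tapply(wts * (cols - 1), comp, sum) / sw
  y <- tapply(wts * (rows - 1), comp, sum) / sw
  score <- tapply(wts, comp, max)
  data.frame(x = as.numeric(x), y = as.numeric(y), score = as.numeric(score))
}

#' Save or load a SpotNetModel
#'
#' Models are serialized with R's native RDS format.
#'
#' @param model a [SpotNetModel-class].
#' @param path file path (conventionally under `models/`).
#' @return `loadSpotNet()` returns the model; `saveSpotNet()` invisibly
#'   returns `path`.
#' @export
saveSpotNet <- function(model, path) {
  stopifnot(is(model, "SpotNetModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSpotNet
#' @export
loadSpotNet <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "SpotNetModel"))
  validObject(model)
  model
}
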