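#' Classical matched-filter spot detection
#'
#' Deterministic localization of diffraction-limited spots.  The image is
#' band-passed with a difference of Gaussians (widths `psfSigma` and
#' `3 * psfSigma`), candidate spots are local maxima of the response with a
#' minimum mutual separation of `2 * psfSigma`, retained where the response
#' exceeds the robust background level (median of the response) by
#' `thresholdK` robust spreads (MAD).  Subpixel positions are intensity-
#' weighted centroids of the non-negative response in a square window of
#' half-width `2 * psfSigma` (rounded up).  The detector is fully
#' deterministic for a fixed input.
#'
#' @param micrograph a [Micrograph-class] or numeric matrix.
#' @param psfSigma expected PSF width, px.
#' @param thresholdK detection threshold in robust-spread units.
#' @return A data.frame with columns `x`, `y` (0-based subpixel pixel-center
#'   coordinates) and `score` (peak response in robust-spread units).
#' @examples
#' sc <- simulateScene(SceneConfig(pixels = 128L, w = 40e-6, seed = 3L))
#' loc <- detectClassical(sc$micrograph)
#' nrow(loc)
#' @export
detectClassical <- function(micrograph, psfSigma = 1.3, thresholdK = 5) {
  img <- if (is(micrograph, "Micrograph")) micrograph@pixels else micrograph
  stopifnot(psfSigma > 0)
  if (any(!is.finite(img)))
    stop("micrograph contains non-finite pixels (corrupt input)")
  n <- nrow(img)

  # replicate-pad before smoothing: the FFT blur is circular and would
  # otherwise wrap bright spots across to the opposite border
  pad <- ceiling(10 * psfSigma)
  idx <- pmin(pmax(seq_len(n + 2L * pad) - pad, 1L), n)
  padded <- img[idx, idx]
  core <- pad + seq_len(n)
  bp <- (EBImage::gblur(padded, sigma = psfSigma) -
         EBImage::gblur(padded, sigma = 3 * psfSigma))[core, core]
  med <- stats::median(bp)
  spread <- stats::mad(bp)
  if (spread == 0) spread <- .Machine$double.eps
  thr <- med + thresholdK * spread

  # local maxima with minimum separation 2 * psfSigma: a grayscale dilation
  # (max filter) over a disc of that radius
  brushSize <- 2L * ceiling(2 * psfSigma) + 1L
  localMax <- EBImage::dilate(bp, EBImage::makeBrush(brushSize, "disc"))
  cand <- which(bp >= localMax - 1e-9 & bp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  # exact response ties on a plateau (e.g. a spot centred between pixels)
  # survive the max filter twice; keep one candidate per separation radius
  ord <- order(bp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sepSq <- (2 * psfSigma)^2
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1L]) {
    prev <- which(keep[seq_len(i - 1L)])
    if (any((cand[prev, 1L] - cand[i, 1L])^2 +
            (cand[prev, 2L] - cand[i, 2L])^2 <= sepSq))
      keep[i] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]

  half <- ceiling(2 * psfSigma)
  pos <- matrix(NA_real_, nrow(cand), 2L)
  score <- numeric(nrow(cand))
  wpos <- pmax(bp - med, 0)
  for (i in seq_len(nrow(cand))) {
    r0 <- cand[i, 1L]; c0 <- cand[i, 2L]
    rows <- max(1L, r0 - half):min(n, r0 + half)
    cols <- max(1L, c0 - half):min(n, c0 + half)
    wts <- wpos[rows, cols, drop = FALSE]
    tw <- sum(wts)
    if (tw <= 0) { pos[i, ] <- c(c0 - 1, r0 - 1) } else {
      pos[i, 1L] <- sum(rep(cols - 1, each = length(rows)) * wts) / tw
      pos[i, 2L] <- sum(rep(rows - 1, times = length(cols)) * wts) / tw
    }
    score[i] <- (bp[r0, c0] - med) / spread
  }
  data.frame(x = pos[, 1L], y = pos[, 2L], score = score)
}

#' Match detected localizations against ground truth
#'
#' Greedy nearest-neighbour matching within a radius: detection-truth pairs
#' are accepted in order of increasing distance, each truth spot and each
#' detection matched at most once.  Used to score detectors on simulated
#' scenes.
#'
#' @param detections data.frame with columns `x`, `y`.
#' @param truth a [GroundTruth-class] or data.frame with columns `x`, `y`.
#' @param radius matching radius, px.
#' @return A list with `nMatched`, `precision`, `recall`, `f1`, and the
#'   matched index pairs.
#' @export
matchLocalizations <- function(detections, truth, radius = 2) {
  tr <- if (is(truth, "GroundTruth")) emitters(truth) else truth
  nd <- nrow(detections); nt <- nrow(tr)
  if (nd == 0L || nt == 0L)
    return(list(nMatched = 0L,
      precision = if (nd == 0L) NA_real_ else 0,
      recall = if (nt == 0L) NA_real_ else 0,
      f1 = 0, pairs = cbind(detection = integer(0), truth = integer(0))))
  d2 <- outer(detections$x, tr$x, "-")^2 + outer(detections$y, tr$y, "-")^2
  d2[d2 > radius^2] <- NA
  ord <- order(d2, na.last = NA)
  usedD <- logical(nd); usedT <- logical(nt)
  pd <- integer(0); pt <- integer(0)
  for (k in ord) {
    i <- (k - 1L) %% nd + 1L
    j <- (k - 1L) %/% nd + 1L
    if (!usedD[i] && !usedT[j]) {
      usedD[i] <- TRUE; usedT[j] <- TRUE
      pd <- c(pd, i); pt <- c(pt, j)
    }
  }
  m <- length(pd)
  precision <- m / nd
  recall <- m / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(nMatched = m, precision = precision, recall = recall, f1 = f1,
       pairs = cbind(detection = pd, truth = pt))
}
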