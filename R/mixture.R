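#' Fit a K-component Gaussian curve combination to an intensity histogram
#'
#' Decomposes the histogram of background-corrected spot intensities into
#' `K` Gaussian components interpreted as monomers, dimers, trimers, ...
#' The histogram uses Freedman-Diaconis bins and the model
#' `counts_i = sum_k A_k * binwidth * dnorm(mid_i; mu_k, sigma_k)` is fitted
#' to the bin counts by bounded Levenberg-Marquardt least squares with
#' Poisson weights `1 / max(count, 1)`, so `A_k` is directly the number of
#' spots in component `k`.  Initialization places `mu_1` at the histogram's
#' first mode, `mu_k = k * mu_1`, `sigma_k = 0.25 * mu_1`, and areas from
#' the counts near each initial mean.  With `constrained = TRUE` the means
#' are harmonic (`mu_k = k * mu_1`) and widths scale as `sqrt(k)`.
#'
#' @param intensities background-corrected spot intensities (counts); `NA`s
#'   (excluded spots) are dropped.  At least 100 values are required.
#' @param K number of components (1 to 4).
#' @param constrained apply the harmonic mean/width constraints.
#' @return A [MixtureFit-class]; if the optimizer fails or any fitted area
#'   is non-positive, the object carries `converged = FALSE` and the last
#'   parameter values as diagnostics.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(700, 1000, 200), rnorm(200, 2000, 280), rnorm(100, 3000, 350))
#' fit <- fitIntensityMixture(x, K = 3)
#' correctionFactor(fit)
#' @export
fitIntensityMixture <- function(intensities, K = 3L, constrained = FALSE) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 100L)
    stop("at least 100 non-excluded intensities are required for a ",
         "histogram fit (got ", length(x), ")")
  if (!K %in% 1:4) stop("K must be in 1..4")
  K <- as.integer(K)

  hh <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- hh$mids; counts <- hh$counts
  bw <- diff(hh$breaks)[1L]
  wts <- 1 / sqrt(pmax(counts, 1))

  # first mode of the lightly smoothed histogram
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2L)
  sm[is.na(sm)] <- counts[is.na(sm)]
  mu1 <- mids[which.max(sm)]
  if (mu1 <= 0) mu1 <- max(stats::median(x), bw)
  s1 <- 0.25 * mu1
  # spots within +-1 sigma of each harmonic mean hold ~68% of a component
  areaInit <- vapply(seq_len(K), function(k)
    max(sum(counts[abs(mids - k * mu1) < s1]) / 0.68, 1), numeric(1))
  areaInit <- pmin(areaInit, length(x))

  model <- function(par) {
    if (constrained) {
      A <- par[seq_len(K)]; mu <- par[K + 1L] * seq_len(K)
      sg <- par[K + 2L] * sqrt(seq_len(K))
    } else {
      A <- par[seq_len(K)]; mu <- par[K + seq_len(K)]
      sg <- par[2L * K + seq_len(K)]
    }
    rowSums(vapply(seq_len(K), function(k)
      A[k] * bw * stats::dnorm(mids, mu[k], sg[k]), numeric(length(mids))))
  }
  par0 <- if (constrained) c(areaInit, mu1, s1) else
    c(areaInit, mu1 * seq_len(K), rep(s1, K))
  lower <- if (constrained) c(rep(0, K), bw, bw / 4) else
    c(rep(0, K), rep(min(mids) - bw, K), rep(bw / 4, K))

  fitOk <- TRUE
  res <- try(minpack.lm::nls.lm(par = par0,
      fn = function(p) (counts - model(p)) * wts,
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(res, "try-error")) {
    par <- par0; rss <- NA_real_; fitOk <- FALSE
  } else {
    par <- res$par
    rss <- sum(res$fvec^2)
    if (!res$info %in% 1:4) fitOk <- FALSE
  }
  if (constrained) {
    A <- par[seq_len(K)]; mu <- par[K + 1L] * seq_len(K)
    sg <- par[K + 2L] * sqrt(seq_len(K))
  } else {
    A <- par[seq_len(K)]; mu <- par[K + seq_len(K)]
    sg <- par[2L * K + seq_len(K)]
    ord <- order(mu)
    A <- A[ord]; mu <- mu[ord]; sg <- sg[ord]
  }
  if (any(A <= 0)) fitOk <- FALSE
  totalArea <- sum(A)
  if (fitOk && abs(totalArea - length(x)) > 0.1 * length(x))
    warning("fitted component areas differ from the spot count by more ",
            "than 10%")
  new("MixtureFit", K = K, area = A, mean = mu, sigma = sg,
      breaks = hh$breaks, counts = as.numeric(counts), rss = rss,
      converged = fitOk, constrained = constrained)
}

#' Aggregate correction factor from a mixture fit
#'
#' The mean number of nanoparticles per detected spot,
#' `R = sum_k k * A_k / sum_k A_k`, computed from the areas of the fitted
#' Gaussian components (component `k` holding `k` particles).  Multiplying
#' the spot count by `R` converts spots to particles.
#'
#' @param fit a [MixtureFit-class].
#' @return The correction factor `R` (dimensionless, `>= 1`; exactly 1 for
#'   `K = 1`).
#' @examples
#' # areas 60/30/10 -> R = (60 + 60 + 30) / 100 = 1.5
#' @export
correctionFactor <- function(fit) {
  stopifnot(is(fit, "MixtureFit"))
  sum(seq_len(fit@K) * fit@area) / sum(fit@area)
}

#' Choose the number of mixture components by information criterion
#'
#' Fits `K = 1 .. KMax` with [fitIntensityMixture()] and selects the `K`
#' minimizing an AIC-style criterion on the weighted histogram residuals,
#' `n_bins * log(RSS_w / n_bins) + 2 * (3K)`; near-ties (within 2 units)
#' resolve toward the smaller `K`.  Non-converged fits are skipped.
#'
#' @param intensities background-corrected spot intensities.
#' @param KMax largest number of components to consider (<= 4).
#' @param constrained passed to [fitIntensityMixture()].
#' @return The selected integer `K`.
#' @export
selectComponents <- function(intensities, KMax = 3L, constrained = FALSE) {
  stopifnot(KMax <= 4L, KMax >= 1L)
  ic <- rep(NA_real_, KMax)
  for (K in seq_len(KMax)) {
    # candidate fits at the wrong K legitimately mismatch the spot count;
    # only the selected model's diagnostics matter
    fit <- try(suppressWarnings(
      fitIntensityMixture(intensities, K, constrained)), silent = TRUE)
    if (inherits(fit, "try-error") || !fit@converged) next
    nb <- length(fit@counts)
    ic[K] <- nb * log(fit@rss / nb) + 2 * 3 * K
  }
  if (all(is.na(ic))) stop("no mixture fit converged for any K")
  best <- min(ic, na.rm = TRUE)
  which(!is.na(ic) & ic <= best + 2)[1L]
}

#' Plot an intensity histogram with its fitted Gaussian components
#'
#' @param fit a [MixtureFit-class].
#' @param main plot title.
#' @return Invisibly, `NULL`; draws on the active device.
#' @export
plotMixtureFit <- function(fit, main = "Spot intensity histogram") {
  mids <- (fit@breaks[-1L] + fit@breaks[-length(fit@breaks)]) / 2
  bw <- diff(fit@breaks)[1L]
  graphics::plot(mids, fit@counts, type = "h", lwd = 3, col = "grey70",
    xlab = "corrected intensity (counts)", ylab = "spots per bin",
    main = main)
  xx <- seq(min(fit@breaks), max(fit@breaks), length.out = 400L)
  tot <- rep(0, length(xx))
  for (k in seq_len(fit@K)) {
    yy <- fit@area[k] * bw * stats::dnorm(xx, fit@mean[k], fit@sigma[k])
    graphics::lines(xx, yy, col = k + 1L, lwd = 1.5)
    tot <- tot + yy
  }
  graphics::lines(xx, tot, lwd = 2)
  invisible(NULL)
}
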