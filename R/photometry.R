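#' Global background level from random off-spot sites
#'
#' Estimates the flat per-pixel background (photon-upconversion mode) by
#' averaging pixels inside aperture-sized discs at random sites placed far
#' from every localized spot.  The admissible region is every pixel at least
#' `exclusionRadius` from every localization and at least `apertureRadius`
#' from the border; site centers are drawn uniformly from it.
#'
#' @param micrograph a [Micrograph-class] or numeric matrix.
#' @param localizations data.frame with columns `x`, `y` (0-based).
#' @param nSites number of random background sites (default 100, the
#'   assay's convention).
#' @param exclusionRadius minimum distance of a site from any spot, px.
#' @param apertureRadius disc radius of each site, px.
#' @param seed integer seed for site placement.
#' @return Mean background, counts per pixel.
#' @export
estimateBackgroundGlobal <- function(micrograph, localizations,
    nSites = 100L, exclusionRadius = 15.6, apertureRadius = 3.9,
    seed = 1L) {
  img <- if (is(micrograph, "Micrograph")) micrograph@pixels else micrograph
  n <- nrow(img)
  admissible <- matrix(TRUE, n, n)
  if (nrow(localizations) > 0L) {
    mask <- matrix(1, n, n)
    rr <- pmin(pmax(round(localizations$y) + 1L, 1L), n)
    cc <- pmin(pmax(round(localizations$x) + 1L, 1L), n)
    mask[cbind(rr, cc)] <- 0
    admissible <- EBImage::distmap(mask) >= exclusionRadius
  }
  m <- ceiling(apertureRadius)
  border <- matrix(FALSE, n, n)
  border[(1L + m):(n - m), (1L + m):(n - m)] <- TRUE
  admissible <- admissible & border
  # sites may overlap each other (their mean is unaffected), so the
  # requirement is enough distinct admissible centers, not disjoint discs
  if (sum(admissible) < 10 * nSites)
    stop("fewer than 10x", nSites, " admissible background pixels remain: ",
         "the field is too crowded for a global background estimate")
  sites <- withSeed(seed, sample(which(admissible), nSites))
  total <- 0; count <- 0L
  for (s in sites) {
    y0 <- (s - 1L) %% n        # 0-based row
    x0 <- (s - 1L) %/% n       # 0-based col
    ind <- apertureIndices(n, x0, y0, apertureRadius)
    total <- total + sum(img[ind])
    count <- count + nrow(ind)
  }
  total / count
}

#' Local background from a median annulus around one spot
#'
#' Median pixel value in the annulus `innerRadius < r <= outerRadius` around
#' the localization, the per-spot background estimator for fluorescence-mode
#' micrographs whose background varies across the field.  The median makes
#' the estimate robust to a neighbouring spot covering part of the annulus.
#'
#' @param micrograph a [Micrograph-class] or numeric matrix.
#' @param x,y 0-based pixel-center spot coordinates.
#' @param innerRadius,outerRadius annulus radii, px (`outer > inner`).
#' @return Background, counts per pixel; `NA` with a warning if the annulus
#'   leaves the image.
#' @export
estimateBackgroundLocal <- function(micrograph, x, y, innerRadius = 3.9,
    outerRadius = 7.8) {
  img <- if (is(micrograph, "Micrograph")) micrograph@pixels else micrograph
  stopifnot(outerRadius > innerRadius)
  n <- nrow(img)
  if (x - outerRadius < -0.5 || x + outerRadius > n - 0.5 ||
      y - outerRadius < -0.5 || y + outerRadius > n - 0.5)
    return(NA_real_)
  outer <- apertureIndices(n, x, y, outerRadius)
  keep <- ((outer[, "col"] - 1) - x)^2 + ((outer[, "row"] - 1) - y)^2 >
    innerRadius^2
  stats::median(img[outer[keep, , drop = FALSE]])
}

#' Background-corrected aperture photometry with overlap exclusion
#'
#' Measures the integrated intensity of each localized spot as the pixel sum
#' inside a circular aperture, subtracts the background (`backgroundMode
#' "global"`: one flat level from [estimateBackgroundGlobal()];
#' `"local"`: per-spot annulus median from [estimateBackgroundLocal()])
#' scaled by the aperture's pixel area, and flags spots whose measurement is
#' unreliable: `excludedOverlap` when any neighbour lies closer than
#' `minSeparation` (mutual interference — exclusion is symmetric), and
#' `borderExcluded` when the aperture (or annulus) touches the image border.
#' Excluded spots carry `NA` corrected intensity but still count toward the
#' spot number N used by the counting assay.
#'
#' @param micrograph a [Micrograph-class] or numeric matrix.
#' @param localizations data.frame with columns `x`, `y`.
#' @param apertureRadius aperture radius, px (default `3 * psfSigma`).
#' @param minSeparation neighbour distance below which both spots are
#'   excluded from photometry, px (default `2 * apertureRadius`).
#' @param backgroundMode `"global"` or `"local"`; the default `"auto"`
#'   follows the imaging mode (upconversion -> global, fluorescence ->
#'   local).
#' @param nSites,exclusionRadius,seed passed to
#'   [estimateBackgroundGlobal()].
#' @param innerRadius,outerRadius passed to [estimateBackgroundLocal()].
#' @return A data.frame with one row per localization: `x`, `y`, `raw`,
#'   `background` (counts per px), `corrected`, `excludedOverlap`,
#'   `borderExcluded`.
#' @examples
#' sc <- simulateScene(SceneConfig(pixels = 128L, w = 40e-6, seed = 4L))
#' loc <- detectClassical(sc$micrograph)
#' spots <- measureIntensities(sc$micrograph, loc)
#' head(spots)
#' @export
measureIntensities <- function(micrograph, localizations,
    apertureRadius = 3.9, minSeparation = 2 * apertureRadius,
    backgroundMode = c("auto", "global", "local"), nSites = 100L,
    exclusionRadius = 4 * apertureRadius,
    innerRadius = apertureRadius, outerRadius = 2 * apertureRadius,
    seed = 1L) {
  backgroundMode <- match.arg(backgroundMode)
  img <- if (is(micrograph, "Micrograph")) micrograph@pixels else micrograph
  if (backgroundMode == "auto")
    backgroundMode <- if (is(micrograph, "Micrograph") &&
        imagingMode(micrograph) == "fluorescence") "local" else "global"
  n <- nrow(img)
  ns <- nrow(localizations)
  x <- localizations$x; y <- localizations$y

  excludedOverlap <- logical(ns)
  if (ns > 1L) {
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    diag(d2) <- Inf
    excludedOverlap <- apply(d2 < minSeparation^2, 1L, any)
  }
  borderLimit <- if (backgroundMode == "local")
    max(apertureRadius, outerRadius) else apertureRadius
  borderExcluded <- x - borderLimit < -0.5 | x + borderLimit > n - 0.5 |
                    y - borderLimit < -0.5 | y + borderLimit > n - 0.5

  globalBg <- if (backgroundMode == "global")
    estimateBackgroundGlobal(img, localizations, nSites = nSites,
      exclusionRadius = exclusionRadius, apertureRadius = apertureRadius,
      seed = seed) else NA_real_

  raw <- rep(NA_real_, ns); bg <- rep(NA_real_, ns)
  corrected <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    if (borderExcluded[i]) next
    ind <- apertureIndices(n, x[i], y[i], apertureRadius)
    raw[i] <- sum(img[ind])
    bg[i] <- if (backgroundMode == "global") globalBg else
      estimateBackgroundLocal(img, x[i], y[i], innerRadius, outerRadius)
    if (!excludedOverlap[i])
      corrected[i] <- raw[i] - bg[i] * nrow(ind)
  }
  data.frame(x = x, y = y, raw = raw, background = bg,
             corrected = corrected, excludedOverlap = excludedOverlap,
             borderExcluded = borderExcluded)
}
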