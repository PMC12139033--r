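#' Convert spot counts per micrograph to a stock molar concentration
#'
#' The counting assay: particles immobilized in a cast agarose layer of
#' pre-collapse thickness `h` over a field of width `w` sample a known
#' volume `h * w^2`, so the molar concentration in the gel is
#' `c = N * R / (h * w^2 * N_A)` (in mol/m^3; divided by 10^3 for mol/L),
#' and the stock concentration is that times the dilution factor `D`.
#' `N` is the mean number of detected spots per micrograph — all spots,
#' including those excluded from photometry — and `R` the aggregate
#' correction factor converting spots to particles.
#'
#' @param N numeric vector of per-micrograph spot counts (one microlayer
#'   preparation), or a list of such vectors (one per preparation).
#' @param R aggregate correction factor from [correctionFactor()].
#' @param h pre-collapse gel thickness, m.
#' @param w micrograph field width, m.
#' @param D dilution factor of the imaged sample relative to the stock
#'   (>= 1).
#' @return A [CountingResult-class]; per-preparation concentrations, their
#'   mean, and the between-preparation SD.
#' @examples
#' # 1344 spots, R = 1.66, 38 um layer, 300 um field:
#' res <- concentrationFromCounts(1344, R = 1.66, h = 38e-6, w = 300e-6)
#' stockConcentration(res)   # ~1.08e-12 mol/L
#' @export
concentrationFromCounts <- function(N, R, h, w, D = 1) {
  if (!is.list(N)) N <- list(N)
  nAll <- unlist(N)
  if (length(nAll) == 0L) stop("N is empty")
  if (any(nAll < 0)) stop("spot counts must be non-negative")
  if (h <= 0 || w <= 0) stop("h and w must be positive")
  if (D < 1) stop("dilution factor D must be >= 1")
  if (R < 1) stop("correction factor R must be >= 1")

  cPrep <- vapply(N, function(n)
    mean(n) * R * D / (h * w^2 * .AVOGADRO) * 1e-3, numeric(1))
  meanN <- mean(nAll)
  new("CountingResult", N = N, R = R, h = h, w = w, D = D,
    particlesPerMicrograph = meanN * R,
    spotDensity = meanN / (w * 1e3)^2,
    particleDensity = meanN * R / (w * 1e3)^2,
    cPerPreparation = cPrep,
    cStock = mean(cPrep),
    cSD = if (length(cPrep) > 1L) stats::sd(cPrep) else NA_real_)
}

#' Run the full counting assay on a set of micrographs
#'
#' Chains detection, photometry, the intensity-mixture fit and the
#' concentration conversion: each micrograph is localized (classical
#' matched filter by default, or the trained segmentation model), spots are
#' measured with background correction, the background-corrected intensities
#' of all micrographs are pooled into one histogram fit giving the
#' aggregate correction factor `R`, and the per-micrograph spot counts are
#' converted to the stock concentration.
#'
#' @param micrographs a list of [Micrograph-class] objects (one microlayer
#'   preparation), or a list of such lists (one per preparation).
#' @param h pre-collapse gel thickness, m.
#' @param D dilution factor to the stock.
#' @param method `"classical"` or `"net"`.
#' @param model a [SpotNetModel-class], required for `method = "net"`.
#' @param psfSigma,thresholdK detection parameters, see [detectClassical()].
#' @param K mixture components; ignored when `selectK = TRUE`.
#' @param selectK choose `K` by [selectComponents()].
#' @param apertureRadius,backgroundMode photometry parameters, see
#'   [measureIntensities()].
#' @param seed seed for the stochastic photometry background sites.
#' @return A [CountingResult-class] with the pooled [MixtureFit-class]
#'   attached as attribute `"fit"` and the per-micrograph spot tables as
#'   attribute `"spots"`.
#' @export
endToEndCounting <- function(micrographs, h, D = 1,
    method = c("classical", "net"), model = NULL, psfSigma = 1.3,
    thresholdK = 5, K = 3L, selectK = FALSE,
    apertureRadius = 3 * psfSigma,
    backgroundMode = c("auto", "global", "local"), seed = 1L) {
  method <- match.arg(method)
  backgroundMode <- match.arg(backgroundMode)
  if (method == "net" && is.null(model))
    stop("method = 'net' requires a trained SpotNetModel")
  if (is(micrographs, "Micrograph")) micrographs <- list(micrographs)
  if (!is.list(micrographs[[1L]])) preps <- list(micrographs)
  else preps <- micrographs
  allMg <- unlist(preps)
  wset <- unique(vapply(allMg, fieldWidth, numeric(1)))
  if (length(wset) != 1L)
    stop("all micrographs must share the same field width")

  spotTables <- list()
  Nlist <- vector("list", length(preps))
  pooled <- numeric(0)
  for (p in seq_along(preps)) {
    Np <- numeric(length(preps[[p]]))
    for (i in seq_along(preps[[p]])) {
      mg <- preps[[p]][[i]]
      loc <- if (method == "classical")
        detectClassical(mg, psfSigma = psfSigma, thresholdK = thresholdK)
      else detectNet(model, mg)
      spots <- measureIntensities(mg, loc, apertureRadius = apertureRadius,
        backgroundMode = backgroundMode, seed = seed + 97L * p + i)
      Np[i] <- nrow(spots)
      pooled <- c(pooled, spots$corrected[is.finite(spots$corrected)])
      spotTables[[length(spotTables) + 1L]] <- spots
    }
    Nlist[[p]] <- Np
  }

  if (selectK) K <- selectComponents(pooled, KMax = max(K, 3L))
  fit <- fitIntensityMixture(pooled, K = K)
  R <- max(correctionFactor(fit), 1)
  res <- concentrationFromCounts(Nlist, R = R, h = h, w = wset, D = D)
  attr(res, "fit") <- fit
  attr(res, "spots") <- spotTables
  res
}
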