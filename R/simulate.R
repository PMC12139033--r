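#' Simulate a ground-truthed nanoparticle micrograph
#'
#' Renders a synthetic micrograph of nanoparticles immobilized in a collapsed
#' agarose microlayer.  The number of emitters (diffraction-limited spots) is
#' Poisson with mean `c * 10^3 * h * w^2 * N_A / E[multiplicity]`, i.e. the
#' expected number of particles in the cast gel volume divided by the mean
#' aggregate size.  Each emitter is placed uniformly in the field and rendered
#' as a pixel-integrated isotropic Gaussian of width `psfSigma`, with
#' integrated intensity equal to the sum of `multiplicity` independent
#' monomer brightness draws (each particle in an aggregate carries its own
#' brightness, so an aggregate of `k` particles has mean intensity `k`
#' times the monomer mean and width scaling with `sqrt(k)`).  The
#' background is flat in upconversion mode, or a constant plus a smooth
#' long-correlation random field in fluorescence mode.  Poisson shot noise is
#' applied to signal plus background, followed by Gaussian readout noise;
#' pixel values are rounded to integer counts and clipped at zero, emulating
#' a camera.  The same seed yields bit-identical output.
#'
#' @param config a [SceneConfig-class].
#' @return A list with elements `micrograph` ([Micrograph-class]) and
#'   `groundTruth` ([GroundTruth-class]).
#' @examples
#' sc <- simulateScene(SceneConfig(pixels = 128L, w = 40e-6, seed = 2L))
#' spotCount(sc$groundTruth)
#' @export
simulateScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  f <- config@multiplicityFractions
  meanMult <- sum(seq_along(f) * f)
  # cast-gel volume h*w^2 m^3 = 10^3 L; expected particles = c * V[L] * N_A
  expParticles <- config@concentration * 1e3 * config@h * config@w^2 * .AVOGADRO
  expSpots <- expParticles / meanMult
  px <- config@pixels
  if (expSpots > 0.25 * px^2)
    stop("expected spot count exceeds 0.25 * pixels^2: spots are no longer ",
         "sparse (overcrowded scene)")

  withSeed(config@seed, {
    nSpots <- stats::rpois(1L, expSpots)
    # uniform physical position; 0-based pixel-center coordinate in
    # [-0.5, px - 0.5): physical x = (x_px + 0.5) * w / px
    x <- stats::runif(nSpots, -0.5, px - 0.5)
    y <- stats::runif(nSpots, -0.5, px - 0.5)
    mult <- if (nSpots > 0L)
      sample.int(length(f), nSpots, replace = TRUE, prob = f) else integer(0)
    drawMonomer <- function(k) {
      if (config@monomerDistribution == "lognormal") {
        sdlog <- sqrt(log(1 + config@monomerCV^2))
        stats::rlnorm(k, log(config@monomerMean) - sdlog^2 / 2, sdlog)
      } else
        pmax(stats::rnorm(k, config@monomerMean,
                          config@monomerCV * config@monomerMean), 0)
    }
    intensity <- vapply(mult, function(k) sum(drawMonomer(k)), numeric(1))

    signal <- renderSpots(px, x, y, intensity, config@psfSigma)
    bg <- matrix(config@backgroundLevel, px, px)
    if (config@mode == "fluorescence" && config@backgroundAmplitude > 0)
      bg <- pmax(bg + smoothField(px, config@backgroundAmplitude,
                                  config@backgroundCorrelation), 0)
    ideal <- signal + bg
    noisy <- matrix(stats::rpois(px^2, pmax(ideal, 0)), px, px)
    if (config@readoutSigma > 0)
      noisy <- noisy + stats::rnorm(px^2, sd = config@readoutSigma)
    pixels <- pmax(round(noisy), 0)

    gt <- new("GroundTruth",
      emitters = data.frame(x = x, y = y, multiplicity = mult,
                            intensity = intensity),
      particleCount = as.integer(sum(mult)), spotCount = as.integer(nSpots))
    list(micrograph = Micrograph(pixels, config@w, config@mode),
         groundTruth = gt)
  })
}

# Add pixel-integrated Gaussian spots to a px x px zero image.
# Coordinates are 0-based pixel-center; pixel i spans [i-0.5, i+0.5].
renderSpots <- function(px, x, y, intensity, psfSigma) {
  img <- matrix(0, px, px)
  r <- ceiling(5 * psfSigma) + 1L
  for (s in seq_along(x)) {
    cols <- max(1L, floor(x[s] + 1 - r)):min(px, ceiling(x[s] + 1 + r))
    rows <- max(1L, floor(y[s] + 1 - r)):min(px, ceiling(y[s] + 1 + r))
    fx <- stats::pnorm(((cols - 1) + 0.5 - x[s]) / psfSigma) -
          stats::pnorm(((cols - 1) - 0.5 - x[s]) / psfSigma)
    fy <- stats::pnorm(((rows - 1) + 0.5 - y[s]) / psfSigma) -
          stats::pnorm(((rows - 1) - 0.5 - y[s]) / psfSigma)
    img[rows, cols] <- img[rows, cols] + intensity[s] * outer(fy, fx)
  }
  img
}

# Smooth zero-mean random field: white noise blurred at the correlation
# length and rescaled to the requested pointwise SD.
smoothField <- function(px, amplitude, correlation) {
  noise <- matrix(stats::rnorm(px^2), px, px)
  # the blur brush must fit inside the image; cap the correlation length
  sigma <- min(correlation, (px - 3) / 7)
  sm <- EBImage::gblur(noise, sigma = sigma)
  sm <- sm - mean(sm)
  s <- stats::sd(as.vector(sm))
  if (s == 0) matrix(0, px, px) else sm * (amplitude / s)
}

#' Write a simulated scene to disk
#'
#' Writes the micrograph as a 16-bit grayscale TIFF, the ground truth as a
#' CSV (`x_px, y_px, multiplicity, intensity`), and a YAML sidecar with the
#' field width and imaging mode so the scene can be re-read losslessly.
#'
#' @param micrograph a [Micrograph-class].
#' @param groundTruth a [GroundTruth-class], or `NULL` to skip the CSV.
#' @param path output TIFF path; the CSV and YAML sidecars take the same
#'   stem with `_truth.csv` and `.yaml` suffixes.
#' @return Invisibly, the paths written.
#' @seealso [readScene()], [readMicrograph()]
#' @export
writeScene <- function(micrograph, groundTruth, path) {
  stopifnot(is(micrograph, "Micrograph"))
  if (max(micrograph@pixels) > 65535)
    stop("pixel values overflow the 16-bit range; lower the scene intensity")
  writeMicrograph(micrograph, path)
  paths <- c(tiff = path)
  if (!is.null(groundTruth)) {
    csv <- sub("\\.tiff?$", "_truth.csv", path)
    em <- emitters(groundTruth)
    utils::write.csv(
      data.frame(x_px = em$x, y_px = em$y, multiplicity = em$multiplicity,
                 intensity = em$intensity),
      csv, row.names = FALSE)
    paths <- c(paths, truth = csv)
  }
  invisible(paths)
}

#' Read back a scene written by [writeScene()]
#'
#' @param path TIFF path previously passed to [writeScene()].
#' @return A list with `micrograph` and, when the truth CSV exists,
#'   `groundTruth`.
#' @export
readScene <- function(path) {
  mg <- readMicrograph(path)
  out <- list(micrograph = mg)
  csv <- sub("\\.tiff?$", "_truth.csv", path)
  if (file.exists(csv)) {
    em <- utils::read.csv(csv)
    out$groundTruth <- new("GroundTruth",
      emitters = data.frame(x = em$x_px, y = em$y_px,
                            multiplicity = as.integer(em$multiplicity),
                            intensity = em$intensity),
      particleCount = as.integer(sum(em$multiplicity)),
      spotCount = as.integer(nrow(em)))
  }
  out
}
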