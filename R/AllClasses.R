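#' @import methods
NULL

#' Avogadro constant (mol^-1), CODATA exact value
#' @noRd
.AVOGADRO <- 6.02214076e23

#' Micrograph: a square pixel raster with physical metadata
#'
#' A single-plane grayscale micrograph together with the physical width of
#' the imaged field and the imaging modality.  Pixel values are photoelectron
#' counts (camera units); the raster is stored as a numeric matrix indexed
#' `[y + 1, x + 1]` where `(x, y)` are 0-based pixel-center coordinates.
#'
#' @slot pixels numeric matrix of pixel values (square).
#' @slot fieldWidth physical width of the field, metres.
#' @slot mode imaging modality, `"upconversion"` or `"fluorescence"`.
#' @export
setClass("Micrograph",
  representation(pixels = "matrix", fieldWidth = "numeric", mode = "character"))

setValidity("Micrograph", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels))
    msg <- c(msg, "pixels must be a numeric matrix")
  if (nrow(object@pixels) != ncol(object@pixels))
    msg <- c(msg, "micrograph must be square")
  if (length(object@fieldWidth) != 1L || is.na(object@fieldWidth) ||
      object@fieldWidth <= 0)
    msg <- c(msg, "fieldWidth must be a single positive number (metres)")
  if (!object@mode %in% c("upconversion", "fluorescence"))
    msg <- c(msg, "mode must be 'upconversion' or 'fluorescence'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Micrograph
#'
#' @param pixels square numeric matrix of pixel values (counts).
#' @param fieldWidth physical field width in metres.
#' @param mode `"upconversion"` (flat, low background) or `"fluorescence"`
#'   (high, spatially varying background).
#' @return A [Micrograph-class] object.
#' @examples
#' mg <- Micrograph(matrix(100, 64, 64), fieldWidth = 20e-6)
#' fieldWidth(mg)
#' @export
Micrograph <- function(pixels, fieldWidth, mode = "upconversion") {
  storage.mode(pixels) <- "double"
  new("Micrograph", pixels = pixels, fieldWidth = fieldWidth, mode = mode)
}

#' SceneConfig: parameters of a synthetic micrograph
#'
#' Describes the ground-truth scene rendered by [simulateScene()]: particle
#' concentration in the cast gel, gel geometry, sensor size, the aggregate
#' multiplicity distribution, the monomer brightness distribution, the point
#' spread function, and the background/noise model of the imaging mode.
#'
#' @slot concentration particle molar concentration in the cast gel, mol/L.
#' @slot h pre-collapse gel thickness, metres.
#' @slot w physical field width, metres.
#' @slot pixels image side length in pixels (>= 64).
#' @slot multiplicityFractions probability vector over aggregate sizes 1..K.
#' @slot monomerMean mean integrated intensity of a monomer, counts.
#' @slot monomerCV coefficient of variation of monomer intensity.
#' @slot monomerDistribution monomer brightness family, `"normal"`
#'   (zero-truncated) or `"lognormal"`.
#' @slot psfSigma Gaussian PSF width, pixels.
#' @slot mode imaging mode, `"upconversion"` or `"fluorescence"`.
#' @slot backgroundLevel mean background, counts per pixel.
#' @slot backgroundAmplitude SD of the smooth background field (fluorescence
#'   mode), counts.
#' @slot backgroundCorrelation correlation length of the background field, px.
#' @slot readoutSigma Gaussian readout noise SD, counts.
#' @slot seed integer seed driving all stochastic steps.
#' @export
setClass("SceneConfig",
  representation(concentration = "numeric", h = "numeric", w = "numeric",
    pixels = "integer", multiplicityFractions = "numeric",
    monomerMean = "numeric", monomerCV = "numeric",
    monomerDistribution = "character", psfSigma = "numeric",
    mode = "character", backgroundLevel = "numeric",
    backgroundAmplitude = "numeric", backgroundCorrelation = "numeric",
    readoutSigma = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- NULL
  f <- object@multiplicityFractions
  if (length(f) < 1L || any(f < 0))
    msg <- c(msg, "multiplicityFractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-12)
    msg <- c(msg, "multiplicityFractions must sum to 1 within 1e-12")
  for (s in c("h", "w", "monomerMean", "psfSigma"))
    if (slot(object, s) <= 0)
      msg <- c(msg, sprintf("%s must be strictly positive", s))
  if (object@concentration < 0)
    msg <- c(msg, "concentration must be non-negative")
  if (object@monomerCV < 0 || object@backgroundLevel < 0 ||
      object@backgroundAmplitude < 0 || object@readoutSigma < 0)
    msg <- c(msg, "noise/background parameters must be non-negative")
  if (object@pixels < 64L)
    msg <- c(msg, "pixels must be >= 64")
  if (!object@mode %in% c("upconversion", "fluorescence"))
    msg <- c(msg, "mode must be 'upconversion' or 'fluorescence'")
  if (!object@monomerDistribution %in% c("normal", "lognormal"))
    msg <- c(msg, "monomerDistribution must be 'normal' or 'lognormal'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SceneConfig
#'
#' Defaults reproduce the photon-upconversion study conditions: a 38 um
#' pre-collapse agarose layer imaged over a 300 um x 300 um field on a
#' 1024 px sensor, at a gel concentration placing ~2231 particles in the
#' field, with monomer/dimer/trimer fractions (0.52, 0.30, 0.18) whose mean
#' multiplicity is the aggregate correction factor 1.66 (so ~1344 spots are
#' expected per micrograph).
#'
#' @param concentration particle molar concentration in the cast gel, mol/L.
#' @param h pre-collapse gel thickness, m.
#' @param w field width, m.
#' @param pixels image side length, px.
#' @param multiplicityFractions probability vector over aggregate sizes.
#' @param monomerMean,monomerCV monomer intensity mean (counts) and
#'   coefficient of variation.
#' @param monomerDistribution monomer brightness family: `"normal"`
#'   (zero-truncated; keeps the histogram modes near-symmetric, as the
#'   Gaussian-curve decomposition of the intensity histogram presumes) or
#'   `"lognormal"` (right-skewed brightness).
#' @param psfSigma PSF width, px.
#' @param mode `"upconversion"` or `"fluorescence"`.
#' @param backgroundLevel,backgroundAmplitude,backgroundCorrelation background
#'   model: flat level (counts/px), smooth-field SD (counts, fluorescence
#'   mode only) and correlation length (px).
#' @param readoutSigma Gaussian readout noise SD, counts.
#' @param seed integer seed.
#' @return A [SceneConfig-class] object.
#' @examples
#' cfg <- SceneConfig(pixels = 128L, w = 40e-6, seed = 7L)
#' @export
SceneConfig <- function(concentration = 1.0825e-12, h = 38e-6, w = 300e-6,
    pixels = 1024L, multiplicityFractions = c(0.52, 0.30, 0.18),
    monomerMean = 2000, monomerCV = 0.25,
    monomerDistribution = c("normal", "lognormal"), psfSigma = 1.3,
    mode = c("upconversion", "fluorescence"), backgroundLevel = NULL,
    backgroundAmplitude = NULL, backgroundCorrelation = 60,
    readoutSigma = 3, seed = 1L) {
  mode <- match.arg(mode)
  monomerDistribution <- match.arg(monomerDistribution)
  if (is.null(backgroundLevel))
    backgroundLevel <- if (mode == "upconversion") 100 else 400
  if (is.null(backgroundAmplitude))
    backgroundAmplitude <- if (mode == "upconversion") 0 else 80
  new("SceneConfig", concentration = concentration, h = h, w = w,
    pixels = as.integer(pixels),
    multiplicityFractions = multiplicityFractions / sum(multiplicityFractions),
    monomerMean = monomerMean, monomerCV = monomerCV,
    monomerDistribution = monomerDistribution, psfSigma = psfSigma,
    mode = mode, backgroundLevel = backgroundLevel,
    backgroundAmplitude = backgroundAmplitude,
    backgroundCorrelation = backgroundCorrelation,
    readoutSigma = readoutSigma, seed = as.integer(seed))
}

#' GroundTruth: emitters underlying a simulated micrograph
#'
#' @slot emitters data.frame with columns `x`, `y` (0-based pixel-center
#'   coordinates, subpixel), `multiplicity` (particles in the spot) and
#'   `intensity` (true integrated intensity, counts).
#' @slot particleCount total number of particles (sum of multiplicities).
#' @slot spotCount number of emitters.
#' @export
setClass("GroundTruth",
  representation(emitters = "data.frame", particleCount = "integer",
    spotCount = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  need <- c("x", "y", "multiplicity", "intensity")
  if (!all(need %in% names(object@emitters)))
    msg <- c(msg, "emitters must have columns x, y, multiplicity, intensity")
  else {
    if (object@spotCount != nrow(object@emitters))
      msg <- c(msg, "spotCount must equal the number of emitters")
    if (object@particleCount != sum(object@emitters$multiplicity))
      msg <- c(msg, "particleCount must equal the sum of multiplicities")
  }
  if (is.null(msg)) TRUE else msg
})

#' MixtureFit: Gaussian decomposition of a spot-intensity histogram
#'
#' Result of fitting a linear combination of `K` Gaussian curves to the
#' histogram of background-corrected spot intensities.  Component `k` is
#' interpreted as spots containing `k` nanoparticles (monomer, dimer, ...);
#' `area[k]` is the number of spots attributed to component `k`.
#'
#' @slot K number of components.
#' @slot area component areas in spot counts.
#' @slot mean component means (ordered increasing), intensity counts.
#' @slot sigma component widths, intensity counts.
#' @slot breaks,counts the histogram the curves were fitted to.
#' @slot rss weighted residual sum of squares of the fit.
#' @slot converged whether the optimizer converged with all areas positive.
#' @slot constrained whether harmonic-mean constraints were applied.
#' @export
setClass("MixtureFit",
  representation(K = "integer", area = "numeric", mean = "numeric",
    sigma = "numeric", breaks = "numeric", counts = "numeric",
    rss = "numeric", converged = "logical", constrained = "logical"))

setValidity("MixtureFit", function(object) {
  msg <- NULL
  if (length(object@area) != object@K || length(object@mean) != object@K ||
      length(object@sigma) != object@K)
    msg <- c(msg, "area, mean, sigma must each have length K")
  if (object@K > 1L && is.unsorted(object@mean))
    msg <- c(msg, "component means must be ordered increasingly")
  if (is.null(msg)) TRUE else msg
})

#' CountingResult: spot counts converted to molar concentration
#'
#' @slot N list of per-micrograph spot counts, one vector per microlayer
#'   preparation.
#' @slot R aggregate correction factor (mean particles per spot).
#' @slot h pre-collapse gel thickness, m.
#' @slot w field width, m.
#' @slot D dilution factor of the imaged sample relative to the stock.
#' @slot particlesPerMicrograph mean spots x R.
#' @slot spotDensity,particleDensity areal densities, mm^-2.
#' @slot cPerPreparation stock molar concentration per preparation, mol/L.
#' @slot cStock mean stock concentration over preparations, mol/L.
#' @slot cSD between-preparation standard deviation, mol/L (NA for a single
#'   preparation).
#' @export
setClass("CountingResult",
  representation(N = "list", R = "numeric", h = "numeric", w = "numeric",
    D = "numeric", particlesPerMicrograph = "numeric",
    spotDensity = "numeric", particleDensity = "numeric",
    cPerPreparation = "numeric", cStock = "numeric", cSD = "numeric"))

setValidity("CountingResult", function(object) {
  msg <- NULL
  if (object@R < 1) msg <- c(msg, "correction factor R must be >= 1")
  if (object@cStock < 0) msg <- c(msg, "concentration must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' TitrationRecord: acid-base titration endpoints and volumes
#'
#' All volumes are in litres and concentrations in mol/L.  The sample is a
#' nanoparticle pellet (washed with dilute HCl, taken from `VStockTaken` of
#' stock) resuspended in `VHClSample` of HCl and titrated with NaOH; the
#' blank titrates `VHClBlank` of the same HCl without particles.
#'
#' @slot VEqSample NaOH endpoint volumes for sample replicates, L.
#' @slot VEqBlank NaOH endpoint volumes for blank replicates, L.
#' @slot cNaOH NaOH concentration, mol/L.
#' @slot VHClBlank volume of HCl titrated in the blank, L.
#' @slot VHClSample volume of HCl in which the pellet was resuspended, L.
#' @slot VStockTaken volume of nanoparticle stock washed and titrated, L.
#' @export
setClass("TitrationRecord",
  representation(VEqSample = "numeric", VEqBlank = "numeric",
    cNaOH = "numeric", VHClBlank = "numeric", VHClSample = "numeric",
    VStockTaken = "numeric"))

setValidity("TitrationRecord", function(object) {
  msg <- NULL
  vols <- c(object@VEqSample, object@VEqBlank, object@VHClBlank,
            object@VHClSample, object@VStockTaken)
  if (any(vols <= 0)) msg <- c(msg, "all volumes must be positive")
  if (object@cNaOH <= 0) msg <- c(msg, "cNaOH must be positive")
  if (length(object@VEqSample) < 1L || length(object@VEqBlank) < 1L)
    msg <- c(msg, "at least one sample and one blank endpoint are required")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TitrationRecord
#'
#' @param VEqSample,VEqBlank replicate NaOH endpoint volumes, L.
#' @param cNaOH NaOH concentration, mol/L (default 2.5 mmol/L).
#' @param VHClBlank,VHClSample HCl volumes in blank and sample, L.
#' @param VStockTaken volume of stock dispersion titrated, L.
#' @return A [TitrationRecord-class] object.
#' @examples
#' rec <- TitrationRecord(VEqSample = 121.1e-6, VEqBlank = c(60.1e-6, 59.9e-6),
#'                        VStockTaken = 300e-6)
#' @export
TitrationRecord <- function(VEqSample, VEqBlank, cNaOH = 2.5e-3,
    VHClBlank = 150e-6, VHClSample = 150e-6, VStockTaken) {
  new("TitrationRecord", VEqSample = VEqSample, VEqBlank = VEqBlank,
    cNaOH = cNaOH, VHClBlank = VHClBlank, VHClSample = VHClSample,
    VStockTaken = VStockTaken)
}

#' ParticleModel: geometry and composition of a nanoparticle
#'
#' @slot diameter sphere diameter, nm (hydrodynamic diameter is used, as in
#'   the assay's structural interpretation).
#' @slot density bulk density, g/cm^3.
#' @slot unitMolarMass molar mass of the bulk repeating unit, g/mol.
#' @slot polymerMolarMass molar mass of the coating polymer chain, g/mol.
#' @slot monomerMolarMass molar mass of the coating monomer unit, g/mol.
#' @export
setClass("ParticleModel",
  representation(diameter = "numeric", density = "numeric",
    unitMolarMass = "numeric", polymerMolarMass = "numeric",
    monomerMolarMass = "numeric"))

setValidity("ParticleModel", function(object) {
  vals <- c(object@diameter, object@density, object@unitMolarMass,
            object@polymerMolarMass, object@monomerMolarMass)
  if (any(vals <= 0)) "all ParticleModel fields must be positive" else TRUE
})

#' Construct a ParticleModel
#'
#' Two presets match the particles characterized by the assay:
#' `"ucnp"` (66 nm NaYF4:Yb/Tm sphere coated with 100 kg/mol poly(acrylic
#' acid), acrylic acid unit 72 g/mol; lattice density 4.21 g/cm^3 and doped
#' NaREF4 unit mass 204.7 g/mol are package defaults, since only the
#' diameter and PAA masses are fixed by the assay description) and
#' `"polystyrene"` (83 nm, 1.0 g/cm^3, styrene unit 104 g/mol).
#'
#' @param preset `"ucnp"`, `"polystyrene"`, or `"custom"`.
#' @param diameter,density,unitMolarMass,polymerMolarMass,monomerMolarMass
#'   override any preset field; see slot documentation for units.
#' @return A [ParticleModel-class] object.
#' @examples
#' ParticleModel("polystyrene")
#' @export
ParticleModel <- function(preset = c("ucnp", "polystyrene", "custom"),
    diameter = NULL, density = NULL, unitMolarMass = NULL,
    polymerMolarMass = NULL, monomerMolarMass = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    ucnp = list(diameter = 66, density = 4.21, unitMolarMass = 204.7,
                polymerMolarMass = 1e5, monomerMolarMass = 72),
    polystyrene = list(diameter = 83, density = 1.0, unitMolarMass = 104,
                polymerMolarMass = 1e5, monomerMolarMass = 72),
    custom = list(diameter = NA_real_, density = NA_real_,
                unitMolarMass = NA_real_, polymerMolarMass = NA_real_,
                monomerMolarMass = NA_real_))
  pick <- function(x, d) if (is.null(x)) d else x
  new("ParticleModel",
    diameter = pick(diameter, def$diameter),
    density = pick(density, def$density),
    unitMolarMass = pick(unitMolarMass, def$unitMolarMass),
    polymerMolarMass = pick(polymerMolarMass, def$polymerMolarMass),
    monomerMolarMass = pick(monomerMolarMass, def$monomerMolarMass))
}

#' SpotNetModel: a small convolutional spot-segmentation model
#'
#' A two-layer fully convolutional pixel classifier: a learned bank of
#' `nFilters` kernels of side `kernelSize`, a ReLU, and a 1x1 logistic
#' output producing a per-pixel spot-probability map.  Inputs are
#' normalized per image by (median, MAD).
#'
#' @slot W1 kernel weights, matrix `kernelSize^2 x nFilters`.
#' @slot b1 first-layer biases.
#' @slot w2 1x1 output weights.
#' @slot b2 output bias.
#' @slot kernelSize kernel side length, px (odd).
#' @slot psfSigma PSF width the model was trained for, px.
#' @slot loss training loss per epoch (binary cross-entropy).
#' @export
setClass("SpotNetModel",
  representation(W1 = "matrix", b1 = "numeric", w2 = "numeric",
    b2 = "numeric", kernelSize = "integer", psfSigma = "numeric",
    loss = "numeric"))

setValidity("SpotNetModel", function(object) {
  msg <- NULL
  if (nrow(object@W1) != object@kernelSize^2)
    msg <- c(msg, "W1 must have kernelSize^2 rows")
  if (ncol(object@W1) != length(object@b1) ||
      ncol(object@W1) != length(object@w2))
    msg <- c(msg, "b1 and w2 must match the number of filters")
  if (object@kernelSize %% 2L == 0L)
    msg <- c(msg, "kernelSize must be odd")
  if (is.null(msg)) TRUE else msg
})
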