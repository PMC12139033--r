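#' @name accessors
#' @title Accessors for npquant data objects
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an npquant S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setMethod("pixelData", "Micrograph", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("fieldWidth", function(object) standardGeneric("fieldWidth"))
#' @rdname accessors
#' @export
setMethod("fieldWidth", "Micrograph", function(object) object@fieldWidth)

#' @rdname accessors
#' @export
setGeneric("imagingMode", function(object) standardGeneric("imagingMode"))
#' @rdname accessors
#' @export
setMethod("imagingMode", "Micrograph", function(object) object@mode)

#' @rdname accessors
#' @export
setGeneric("emitters", function(object) standardGeneric("emitters"))
#' @rdname accessors
#' @export
setMethod("emitters", "GroundTruth", function(object) object@emitters)

#' @rdname accessors
#' @export
setGeneric("particleCount", function(object) standardGeneric("particleCount"))
#' @rdname accessors
#' @export
setMethod("particleCount", "GroundTruth", function(object) object@particleCount)

#' @rdname accessors
#' @export
setGeneric("spotCount", function(object) standardGeneric("spotCount"))
#' @rdname accessors
#' @export
setMethod("spotCount", "GroundTruth", function(object) object@spotCount)

#' @rdname accessors
#' @export
setGeneric("mixtureComponents",
  function(object) standardGeneric("mixtureComponents"))
#' @rdname accessors
#' @export
setMethod("mixtureComponents", "MixtureFit", function(object)
  data.frame(k = seq_len(object@K), area = object@area, mean = object@mean,
             sigma = object@sigma))

#' @rdname accessors
#' @export
setGeneric("stockConcentration",
  function(object) standardGeneric("stockConcentration"))
#' @rdname accessors
#' @export
setMethod("stockConcentration", "CountingResult", function(object)
  object@cStock)

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph: %d x %d px, field %.1f um, %s mode\n",
      nrow(object@pixels), ncol(object@pixels), object@fieldWidth * 1e6,
      object@mode))
  cat(sprintf("  pixel values: [%.0f, %.0f], mean %.1f\n",
      min(object@pixels), max(object@pixels), mean(object@pixels)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d spots, %d particles\n",
      object@spotCount, object@particleCount))
  if (object@spotCount > 0L)
    cat(sprintf("  multiplicities: %s\n",
        paste(sprintf("%dx%d", tabulate(object@emitters$multiplicity),
              seq_len(max(object@emitters$multiplicity))), collapse = " ")))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig (%s mode): %.3g mol/L in gel, h %.1f um, w %.0f um, %d px\n",
      object@mode, object@concentration, object@h * 1e6, object@w * 1e6,
      object@pixels))
  cat(sprintf("  multiplicity fractions: %s (mean multiplicity %.3f)\n",
      paste(signif(object@multiplicityFractions, 3), collapse = ", "),
      sum(seq_along(object@multiplicityFractions) *
          object@multiplicityFractions)))
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: K = %d, %sconverged, RSS %.4g\n", object@K,
      if (object@converged) "" else "NOT ", object@rss))
  print(mixtureComponents(object), row.names = FALSE)
  cat(sprintf("  correction factor R = %.3f\n", correctionFactor(object)))
})

setMethod("show", "CountingResult", function(object) {
  nAll <- unlist(object@N)
  cat(sprintf("CountingResult: %d micrograph(s) in %d preparation(s)\n",
      length(nAll), length(object@N)))
  cat(sprintf("  mean N = %.1f spots, R = %.3f -> %.0f particles/micrograph\n",
      mean(nAll), object@R, object@particlesPerMicrograph))
  cat(sprintf("  densities: %.3g spots/mm^2, %.3g particles/mm^2\n",
      object@spotDensity, object@particleDensity))
  cat(sprintf("  c(stock) = %.4g mol/L (D = %.3g)", object@cStock, object@D))
  if (!is.na(object@cSD))
    cat(sprintf(" +/- %.2g (between-preparation SD)", object@cSD))
  cat("\n")
})

setMethod("show", "SpotNetModel", function(object) {
  cat(sprintf("SpotNetModel: %d filters of %d x %d px, trained %d epochs\n",
      ncol(object@W1), object@kernelSize, object@kernelSize,
      length(object@loss)))
  if (length(object@loss) > 0L)
    cat(sprintf("  final training loss %.5f\n", utils::tail(object@loss, 1)))
})

setMethod("show", "ParticleModel", function(object) {
  cat(sprintf(
    "ParticleModel: d = %.0f nm, rho = %.2f g/cm^3, unit %.1f g/mol, coating %.3g / %.0f g/mol\n",
    object@diameter, object@density, object@unitMolarMass,
    object@polymerMolarMass, object@monomerMolarMass))
})
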