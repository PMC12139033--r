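#' Standardize a NaOH titrant against oxalic acid
#'
#' Oxalic acid is diprotic, so at the equivalence point
#' `c_NaOH = 2 * c_oxalic * V_oxalic / V_NaOH_eq`.
#'
#' @param cOxalic oxalic acid concentration, mol/L.
#' @param VOxalic oxalic acid volume titrated, L.
#' @param VNaOHEq NaOH volume at the endpoint, L.
#' @return NaOH concentration, mol/L.
#' @examples
#' standardizeNaOH(50e-3, 100e-6, 100e-6)   # 0.1 mol/L
#' @export
standardizeNaOH <- function(cOxalic, VOxalic, VNaOHEq) {
  if (cOxalic <= 0 || VOxalic <= 0) stop("concentration and volume must be positive")
  if (VNaOHEq <= 0) stop("VNaOHEq must be positive")
  2 * cOxalic * VOxalic / VNaOHEq
}

#' Carboxyl-group concentration from titration endpoints
#'
#' Blank-corrected titration arithmetic: the NaOH consumed by the surface
#' carboxyls is the sample endpoint volume minus the blank endpoint volume
#' scaled by the HCl volume ratio (`VHClSample / VHClBlank`, since the blank
#' titrates a different HCl volume than the one the pellet is resuspended
#' in; set `scaleBlank = FALSE` for an unscaled blank).  The carboxyl amount
#' `n_COOH = (mean(V_sample) - scaled blank) * c_NaOH` divided by the stock
#' volume titrated gives the stock carboxyl concentration.  The replicate
#' SD of the sample endpoints is propagated to the result.
#'
#' @param record a [TitrationRecord-class].
#' @param scaleBlank scale the blank endpoint by the HCl volume ratio.
#' @return A list: `cCOOH` (mol/L of stock), `sd`, `relSD` (from sample
#'   replicates), `nCOOH` (mol), and `belowLOD` (`TRUE`, with `cCOOH = 0`,
#'   when the blank-corrected signal is negative).
#' @examples
#' rec <- TitrationRecord(VEqSample = 121.1e-6, VEqBlank = 60.0e-6,
#'                        VStockTaken = 300e-6)
#' carboxylConcentration(rec)$cCOOH    # ~0.509 mmol/L
#' @export
carboxylConcentration <- function(record, scaleBlank = TRUE) {
  stopifnot(is(record, "TitrationRecord"))
  validObject(record)
  scale <- if (scaleBlank) record@VHClSample / record@VHClBlank else 1
  blank <- mean(record@VEqBlank) * scale
  dV <- record@VEqSample - blank
  nCOOH <- mean(dV) * record@cNaOH
  belowLOD <- nCOOH < 0
  if (belowLOD) {
    warning("blank-corrected NaOH volume is negative: carboxyl signal is ",
            "below the detection limit")
    nCOOH <- 0
  }
  cCOOH <- nCOOH / record@VStockTaken
  sdC <- if (length(dV) > 1L)
    stats::sd(dV) * record@cNaOH / record@VStockTaken else NA_real_
  list(cCOOH = cCOOH, sd = sdC,
       relSD = if (cCOOH > 0) sdC / cCOOH else NA_real_,
       nCOOH = nCOOH, belowLOD = belowLOD)
}

#' Detection and quantification limits in carboxyl groups per particle
#'
#' The LOD is three standard deviations of the blank titration volume,
#' converted to moles of NaOH and expressed per mole of nanoparticles
#' titrated; the LOQ is ten standard deviations, so `LOQ = (10/3) * LOD`
#' exactly.
#'
#' @param sdBlankVolume SD of the blank NaOH endpoint volume, L.
#' @param cNaOH NaOH concentration, mol/L.
#' @param cNP nanoparticle stock concentration, mol/L.
#' @param VStockTaken stock volume titrated, L.
#' @return Named numeric vector `c(LOD, LOQ)`, groups per particle.
#' @examples
#' detectionLimits(0.86e-6, 2.5e-3, 3.35e-9, 300e-6)   # LOD ~ 6.4e3
#' @export
detectionLimits <- function(sdBlankVolume, cNaOH, cNP, VStockTaken) {
  if (sdBlankVolume < 0 || cNaOH <= 0 || cNP <= 0 || VStockTaken <= 0)
    stop("inputs must be positive (sdBlankVolume may be zero)")
  lod <- 3 * sdBlankVolume * cNaOH / (cNP * VStockTaken)
  c(LOD = lod, LOQ = 10 / 3 * lod)
}

#' Fraction of carboxyls left deprotonated at the titration's starting pH
#'
#' Diagnostic for the acid-wash step: at the pH fixed by the HCl used to
#' protonate the particles, a single-pKa Henderson-Hasselbalch estimate
#' gives the fraction of carboxyl groups still deprotonated (about 3% for
#' 1 mmol/L HCl and pKa 4.5).  This bias is reported, not corrected — it is
#' well within the assay's measurement uncertainty.
#'
#' @param cHCl HCl concentration, mol/L.
#' @param pKa carboxyl pKa (default 4.5, poly(acrylic acid)).
#' @return Fraction deprotonated, in `[0, 1]`.
#' @export
deprotonatedFraction <- function(cHCl = 1e-3, pKa = 4.5) {
  stopifnot(cHCl > 0)
  pH <- -log10(cHCl)
  1 / (1 + 10^(pKa - pH))
}
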