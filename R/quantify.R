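#' Average number of carboxyl groups per nanoparticle
#'
#' The mole-ratio of the carboxyl-group concentration to the nanoparticle
#' concentration; both in mol/L, so the ratio is dimensionless and
#' invariant to a common scale factor.
#'
#' @param cCOOH carboxyl concentration, mol/L (>= 0).
#' @param cNP nanoparticle concentration, mol/L (> 0).
#' @return Groups per particle.
#' @examples
#' groupsPerParticle(0.509e-3, 3.35e-9)   # ~152e3
#' @export
groupsPerParticle <- function(cCOOH, cNP) {
  if (cNP <= 0) stop("cNP must be positive")
  if (cCOOH < 0) stop("cCOOH must be non-negative")
  cCOOH / cNP
}

#' Surface density of functional groups on a spherical particle
#'
#' Groups per nm^2 of sphere surface, `groups / (pi * d^2)`.
#'
#' @param groups groups per particle.
#' @param diameter sphere diameter, nm.
#' @return Density, nm^-2.
#' @examples
#' surfaceDensity(151940, 66)   # ~11 groups per nm^2
#' @export
surfaceDensity <- function(groups, diameter) {
  if (diameter <= 0) stop("diameter must be positive")
  groups / (pi * diameter^2)
}

#' Coating-polymer chains per particle
#'
#' The number of carboxyl-bearing monomer units in one polymer chain is the
#' chain/monomer molar-mass ratio; dividing the groups per particle by it
#' estimates the number of chains bound to one particle.
#'
#' @param groups groups per particle.
#' @param polymerMolarMass chain molar mass, g/mol.
#' @param monomerMolarMass monomer-unit molar mass, g/mol.
#' @return List with `groupsPerChain` and `chains` (both unrounded).
#' @examples
#' chainsPerParticle(151940, 1e5, 72)   # 1388.9 groups/chain, ~110 chains
#' @export
chainsPerParticle <- function(groups, polymerMolarMass, monomerMolarMass) {
  if (polymerMolarMass <= 0 || monomerMolarMass <= 0)
    stop("molar masses must be positive")
  gpc <- polymerMolarMass / monomerMolarMass
  list(groupsPerChain = gpc, chains = groups / gpc)
}

#' Bulk repeating units contained in one spherical particle
#'
#' `(pi/6) * d^3 * rho * N_A / M` with the nm^3 -> cm^3 conversion, giving
#' e.g. styrene units per polystyrene sphere or NaREF4 units per
#' upconversion nanocrystal.
#'
#' @param model a [ParticleModel-class], or a diameter in nm when `density`
#'   and `unitMolarMass` are given directly.
#' @param density bulk density, g/cm^3.
#' @param unitMolarMass repeating-unit molar mass, g/mol.
#' @return Units per particle.
#' @examples
#' bulkUnitsPerParticle(ParticleModel("polystyrene"))   # ~1.7e6
#' @export
bulkUnitsPerParticle <- function(model, density = NULL,
    unitMolarMass = NULL) {
  if (is(model, "ParticleModel")) {
    d <- model@diameter; rho <- model@density; M <- model@unitMolarMass
  } else {
    d <- model; rho <- density; M <- unitMolarMass
  }
  if (is.null(rho) || is.null(M)) stop("density and unitMolarMass required")
  if (d < 0) stop("diameter must be non-negative")
  (pi / 6) * d^3 * 1e-21 * rho * .AVOGADRO / M
}

#' Bulk units per functional group
#'
#' @param bulkUnits bulk repeating units per particle.
#' @param groups functional groups per particle (> 0).
#' @return Units per group (unrounded; report rounded to integer).
#' @examples
#' unitsPerGroup(1.7e6, 38e3)   # ~45 styrene units per carboxyl
#' @export
unitsPerGroup <- function(bulkUnits, groups) {
  if (groups <= 0) stop("groups must be positive")
  bulkUnits / groups
}

#' Assemble the full quantification report
#'
#' Combines a counting result, a titration result and a particle model into
#' the assay's headline numbers — groups per particle with its Monte Carlo
#' standard uncertainty, surface density, coating chains, bulk units and
#' units per group — and optionally writes them as JSON.  Unrounded values
#' are retained in the returned object; display rounding (3 significant
#' figures for concentrations, nearest thousand for group counts, 2 for
#' densities and uncertainties) happens only in the `reported` element.
#'
#' @param counting a [CountingResult-class], or a list with `mean` and `u`
#'   (mol/L) for the nanoparticle concentration.
#' @param titration result of [carboxylConcentration()], or a list with
#'   `mean` and `u` (mol/L) for the carboxyl concentration.
#' @param model a [ParticleModel-class].
#' @param countingRelU relative standard uncertainty of the counting assay
#'   used when `counting` carries no `u` (default 0.08, the assay's type B
#'   inter-method estimate); combined in quadrature with the
#'   between-preparation repeatability when available.
#' @param titrationRelU vector of relative standard uncertainty components
#'   added in quadrature to the titration repeatability when `titration`
#'   carries no `u` (default pipet 1%, syringe 1%, NaOH calibration 1.5%).
#' @param nSamples,seed Monte Carlo settings for [mcPropagateRatio()].
#' @param path optional JSON output path.
#' @return A list with elements `inputs`, `values` (unrounded),
#'   `uncertainty`, and `reported` (display-rounded strings).
#' @export
runReport <- function(counting, titration, model,
    countingRelU = 0.08, titrationRelU = c(0.01, 0.01, 0.015),
    nSamples = 5e6, seed = 1L, path = NULL) {
  stopifnot(is(model, "ParticleModel"))
  if (is(counting, "CountingResult")) {
    cNP <- counting@cStock
    rel <- countingRelU
    if (!is.na(counting@cSD) && counting@cSD > 0)
      rel <- combineQuadrature(c(countingRelU, counting@cSD / cNP))
    cNPu <- rel * cNP
  } else {
    cNP <- counting$mean; cNPu <- counting$u
  }
  if (!is.null(titration$cCOOH)) {
    cCOOH <- titration$cCOOH
    rels <- titrationRelU
    if (!is.null(titration$relSD) && is.finite(titration$relSD))
      rels <- c(titration$relSD, rels)
    cCOOHu <- combineQuadrature(rels) * cCOOH
  } else {
    cCOOH <- titration$mean; cCOOHu <- titration$u
  }

  mc <- mcPropagateRatio(cCOOH, cCOOHu, cNP, cNPu,
                         nSamples = nSamples, seed = seed)
  groups <- groupsPerParticle(cCOOH, cNP)
  dens <- surfaceDensity(groups, model@diameter)
  ch <- chainsPerParticle(groups, model@polymerMolarMass,
                          model@monomerMolarMass)
  bulk <- bulkUnitsPerParticle(model)
  upg <- unitsPerGroup(bulk, groups)

  values <- list(groupsPerParticle = groups,
    groupsPerParticleU = mc$sd, surfaceDensity = dens,
    groupsPerChain = ch$groupsPerChain, chainsPerParticle = ch$chains,
    bulkUnitsPerParticle = bulk, unitsPerGroup = upg)
  reported <- list(
    cNP = sprintf("%.3g mol/L (u = %.2g)", cNP, cNPu),
    cCOOH = sprintf("%.3g mol/L (u = %.2g)", cCOOH, cCOOHu),
    groupsPerParticle = sprintf("%.0f x 10^3 +/- %.0f x 10^3",
      round(groups / 1e3), round(mc$sd / 1e3)),
    surfaceDensity = sprintf("%.2g nm^-2", dens),
    chainsPerParticle = sprintf("%.0f", ch$chains),
    unitsPerGroup = sprintf("%.0f", upg))
  out <- list(
    inputs = list(cNP = cNP, cNPu = cNPu, cCOOH = cCOOH, cCOOHu = cCOOHu,
      model = list(diameter_nm = model@diameter,
        density_g_cm3 = model@density,
        unit_molar_mass_g_mol = model@unitMolarMass,
        polymer_molar_mass_g_mol = model@polymerMolarMass,
        monomer_molar_mass_g_mol = model@monomerMolarMass),
      nSamples = nSamples, seed = seed),
    values = values, uncertainty = mc, reported = reported)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  out
}
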