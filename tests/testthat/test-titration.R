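test_that("NaOH standardization follows diprotic oxalic stoichiometry", {
  expect_equal(standardizeNaOH(50e-3, 100e-6, 100e-6), 100e-3)
  # doubling the endpoint volume halves the concentration
  expect_equal(standardizeNaOH(50e-3, 100e-6, 200e-6), 50e-3)
  expect_equal(standardizeNaOH(50e-3, 80e-6, 81.3e-6), 98.4e-3,
               tolerance = 1e-3)
  expect_error(standardizeNaOH(50e-3, 100e-6, 0), "positive")
})

test_that("carboxyl concentration reproduces the blank-corrected arithmetic", {
  # endpoints built to give (121.1 - 60.0) uL x 2.5 mM / 300 uL = 0.509 mM
  rec <- TitrationRecord(VEqSample = 121.1e-6, VEqBlank = 60.0e-6,
    cNaOH = 2.5e-3, VHClBlank = 150e-6, VHClSample = 150e-6,
    VStockTaken = 300e-6)
  out <- carboxylConcentration(rec)
  expect_equal(out$cCOOH, 0.509e-3, tolerance = 3e-3)
  expect_false(out$belowLOD)
})

test_that("a blank-only sample titrates to zero carboxyl", {
  rec <- TitrationRecord(VEqSample = 40e-6, VEqBlank = 60e-6,
    VHClBlank = 150e-6, VHClSample = 100e-6, VStockTaken = 300e-6)
  out <- carboxylConcentration(rec)   # 60 * 100/150 = 40 -> zero signal
  expect_equal(out$cCOOH, 0)
  expect_false(out$belowLOD)
  # unscaled blank makes the same record negative and flagged
  expect_warning(out2 <- carboxylConcentration(rec, scaleBlank = FALSE),
                 "detection limit")
  expect_true(out2$belowLOD)
  expect_identical(out2$cCOOH, 0)
})

test_that("replicate scatter propagates to the relative SD", {
  base <- 121.1e-6
  reps <- base * (1 + c(-0.03, -0.01, 0, 0.01, 0.03))
  rec <- TitrationRecord(VEqSample = reps, VEqBlank = 60.0e-6,
                         VStockTaken = 300e-6)
  out <- carboxylConcentration(rec)
  expect_equal(out$relSD, sd(reps - 60e-6) / mean(reps - 60e-6),
               tolerance = 1e-9)
})

test_that("carboxyl concentration is linear in the endpoint difference and inverse in stock volume", {
  mk <- function(vs, vstock) carboxylConcentration(TitrationRecord(
    VEqSample = vs, VEqBlank = 60e-6, VStockTaken = vstock))$cCOOH
  d1 <- mk(80e-6, 300e-6)
  d2 <- mk(100e-6, 300e-6)
  expect_equal(d2 / d1, 2)                      # doubled (V - blank)
  expect_equal(mk(80e-6, 150e-6), 2 * d1)       # halved stock volume
})

test_that("detection limits follow the 3/10 sigma definitions", {
  lim <- detectionLimits(0.86e-6, 2.5e-3, 3.35e-9, 300e-6)
  expect_equal(lim[["LOD"]], 6.4e3, tolerance = 0.01)
  expect_equal(lim[["LOQ"]], 21.3e3, tolerance = 0.01)
  expect_equal(lim[["LOQ"]] / lim[["LOD"]], 10 / 3)
  zero <- detectionLimits(0, 2.5e-3, 3.35e-9, 300e-6)
  expect_identical(unname(zero), c(0, 0))
})

test_that("the residual deprotonated fraction at pH 3 is about 3%", {
  expect_equal(deprotonatedFraction(1e-3, 4.5), 0.031, tolerance = 0.02)
})
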