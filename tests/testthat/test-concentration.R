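test_that("spot counts convert to molar concentration by the counting equation", {
  # 1344 spots x R 1.66 in a 38 um x (300 um)^2 gel volume
  res <- concentrationFromCounts(1344, R = 1.66, h = 38e-6, w = 300e-6)
  expect_equal(res@particlesPerMicrograph, 2231, tolerance = 1e-3)
  expect_equal(res@spotDensity, 15e3, tolerance = 0.005)
  expect_equal(stockConcentration(res), 2231.04 / (38e-6 * (300e-6)^2 *
    6.02214076e23) * 1e-3, tolerance = 1e-12)
  expect_equal(stockConcentration(res), 1.083e-12, tolerance = 1e-3)
  # dilution scales linearly to the stock
  resD <- concentrationFromCounts(1344, R = 1.66, h = 38e-6, w = 300e-6,
                                  D = 3093)
  expect_equal(stockConcentration(resD),
               stockConcentration(res) * 3093, tolerance = 1e-12)
  expect_equal(stockConcentration(resD), 3.35e-9, tolerance = 0.005)
})

test_that("the m^3 to litre conversion is dimensionally fixed", {
  # one spot per unit gel volume of 1 m^3 at R = 1 is (1/N_A) mol/m^3,
  # i.e. 1e-3/N_A mol/L
  res <- concentrationFromCounts(1, R = 1, h = 1, w = 1)
  expect_equal(stockConcentration(res), 1e-3 / 6.02214076e23)
})

test_that("replicate preparations report a between-preparation SD", {
  res <- concentrationFromCounts(list(c(1300, 1350, 1320), c(1400, 1380, 1390)),
    R = 1.66, h = 38e-6, w = 300e-6)
  expect_length(res@cPerPreparation, 2L)
  expect_false(is.na(res@cSD))
  expect_equal(res@cPerPreparation[2] / res@cPerPreparation[1],
               mean(c(1400, 1380, 1390)) / mean(c(1300, 1350, 1320)))
})

test_that("invalid counting inputs are rejected", {
  expect_error(concentrationFromCounts(numeric(0), 1.5, 38e-6, 300e-6),
               "empty")
  expect_error(concentrationFromCounts(100, 1.5, -1, 300e-6), "positive")
  expect_error(concentrationFromCounts(100, 0.5, 38e-6, 300e-6), "R")
})

test_that("monomer-only scenes give R near 1 and consistent concentration", {
  mgs <- lapply(301:302, function(s)
    simulateScene(SceneConfig(pixels = 512L, w = 150e-6,
      concentration = 5e-13, multiplicityFractions = 1,
      seed = s))$micrograph)
  res <- endToEndCounting(mgs, h = 38e-6, K = 1L)
  expect_equal(res@R, 1)
  nOnly <- mean(unlist(res@N)) / (38e-6 * (150e-6)^2 * 6.02214076e23) * 1e-3
  expect_equal(stockConcentration(res), nOnly, tolerance = 1e-12)
  expect_equal(stockConcentration(res), 5e-13, tolerance = 0.1)
})

test_that("doubling the true concentration doubles the detected count", {
  n1 <- mean(sapply(311:313, function(s) spotCount(simulateScene(
    SceneConfig(pixels = 256L, w = 75e-6, concentration = 6e-13,
                seed = s))$groundTruth)))
  n2 <- mean(sapply(311:313, function(s) spotCount(simulateScene(
    SceneConfig(pixels = 256L, w = 75e-6, concentration = 1.2e-12,
                seed = 100L + s))$groundTruth)))
  expect_equal(n2 / n1, 2, tolerance = 0.15)
})

test_that("detected spot counts are invariant to image intensity rescaling", {
  sc <- smallScene(41L, pixels = 256L, w = 80e-6)
  img <- pixelData(sc$micrograph)
  expect_identical(nrow(detectClassical(img * 4)), nrow(detectClassical(img)))
})
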