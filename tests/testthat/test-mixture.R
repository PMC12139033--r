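test_that("a single Gaussian sample is recovered within tolerance", {
  set.seed(1)
  x <- rnorm(1500, 1000, 150)
  fit <- fitIntensityMixture(x, K = 1)
  expect_true(fit@converged)
  expect_equal(fit@mean, 1000, tolerance = 0.05)
  expect_equal(fit@sigma, 150, tolerance = 0.05)
  expect_equal(fit@area, 1500, tolerance = 0.1)
  expect_identical(correctionFactor(fit), 1)
})

test_that("three-component area fractions are recovered within 0.05", {
  # monomer/dimer/trimer at 0.7/0.2/0.1, component means 1000/2000/3000
  errs <- sapply(c(2L, 3L, 4L), function(s) {
    x <- simulatedIntensities(2000, seed = s, pixels = 64L, w = 20e-6,
      concentration = 8e-11, monomerMean = 1000,
      multiplicityFractions = c(0.7, 0.2, 0.1))
    fit <- fitIntensityMixture(x, K = 3)
    fit@area / sum(fit@area) - c(0.7, 0.2, 0.1)
  })
  expect_lt(max(abs(rowMeans(errs))), 0.05)
})

test_that("the histogram fit agrees with an EM mixture fit", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  x <- simulatedIntensities(2500, seed = 6L, pixels = 64L, w = 20e-6,
    concentration = 8e-11, monomerMean = 2000)
  fit <- fitIntensityMixture(x, K = 3)
  em <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit@mean), sort(as.numeric(em$parameters$mean)),
               tolerance = 0.1)
  expect_equal(fit@area / sum(fit@area), as.numeric(em$parameters$pro),
               tolerance = 0.12)
})

test_that("correction factor follows the area-weighted mean multiplicity", {
  fit <- new("MixtureFit", K = 3L, area = c(60, 30, 10),
    mean = c(1, 2, 3), sigma = c(0.2, 0.2, 0.2), breaks = 0:1,
    counts = 1, rss = 0, converged = TRUE, constrained = FALSE)
  expect_equal(correctionFactor(fit), 1.5)
  expect_gte(correctionFactor(fit), 1)
})

test_that("the fit is invariant to intensity rescaling", {
  x <- simulatedIntensities(2000, seed = 8L, pixels = 64L, w = 20e-6,
    concentration = 8e-11)
  f1 <- fitIntensityMixture(x, K = 3)
  f2 <- fitIntensityMixture(x * 7, K = 3)
  expect_equal(f2@mean / f1@mean, rep(7, 3), tolerance = 0.02)
  # sigma of the sparse trimer component is sensitive to bin alignment
  expect_equal(f2@sigma / f1@sigma, rep(7, 3), tolerance = 0.15)
  expect_equal(correctionFactor(f2), correctionFactor(f1), tolerance = 0.02)
})

test_that("component selection distinguishes one from three modes", {
  set.seed(5)
  expect_identical(selectComponents(rnorm(1200, 1000, 150), KMax = 3L), 1L)
  x <- simulatedIntensities(2000, seed = 9L, pixels = 64L, w = 20e-6,
    concentration = 8e-11, monomerCV = 0.15)
  expect_identical(selectComponents(x, KMax = 3L), 3L)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fitIntensityMixture(rnorm(50, 100, 1), K = 1), "100")
  expect_error(fitIntensityMixture(rnorm(500, 100, 1), K = 5L), "K")
})
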