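test_that("a uniform image yields zero corrected intensity", {
  img <- matrix(250, 128, 128)
  loc <- data.frame(x = c(40, 90), y = c(40, 90))
  for (mode in c("global", "local")) {
    sp <- measureIntensities(img, loc, apertureRadius = 4,
                             backgroundMode = mode)
    expect_equal(sp$corrected, c(0, 0), tolerance = 1e-9)
    expect_equal(sp$background, c(250, 250), tolerance = 1e-9)
  }
})

test_that("a noiseless Gaussian spot integrates to 2*pi*A*sigma^2 within 1%", {
  n <- 64; A <- 500; sig <- 1.5
  img <- A * exp(-outer((0:(n - 1) - 30.4)^2, (0:(n - 1) - 25.6)^2, "+") /
                   (2 * sig^2))
  sp <- measureIntensities(img, data.frame(x = 25.6, y = 30.4),
    apertureRadius = 4 * sig, backgroundMode = "global",
    exclusionRadius = 20, nSites = 20L)
  expect_equal(sp$corrected, 2 * pi * A * sig^2, tolerance = 0.01)
})

test_that("overlap exclusion is symmetric and keeps both spots in the count", {
  img <- matrix(100, 64, 64)
  loc <- data.frame(x = c(30, 31, 50), y = c(30, 30, 50))
  sp <- measureIntensities(img, loc, apertureRadius = 3,
                           minSeparation = 6, backgroundMode = "global",
                           exclusionRadius = 12)
  expect_identical(sp$excludedOverlap, c(TRUE, TRUE, FALSE))
  expect_identical(nrow(sp), 3L)             # N unchanged by exclusion
  expect_true(all(is.na(sp$corrected[1:2])))  # no corrected intensity
  expect_false(is.na(sp$corrected[3]))
})

test_that("apertures touching the border are flagged, not measured", {
  img <- matrix(100, 64, 64)
  sp <- measureIntensities(img, data.frame(x = c(2, 32), y = c(32, 32)),
    apertureRadius = 4, backgroundMode = "global", exclusionRadius = 8)
  expect_identical(sp$borderExcluded, c(TRUE, FALSE))
  expect_true(is.na(sp$raw[1]))
})

test_that("global background recovers a constant level exactly and a noisy one within 3 SE", {
  img <- matrix(123.4, 128, 128)
  expect_equal(estimateBackgroundGlobal(img, data.frame(x = numeric(0),
    y = numeric(0)), nSites = 20L, apertureRadius = 3), 123.4)

  sc <- smallScene(91L, pixels = 256L, w = 80e-6, concentration = 1e-12)
  loc <- detectClassical(sc$micrograph)
  est <- estimateBackgroundGlobal(sc$micrograph, loc, nSites = 100L,
    exclusionRadius = 12, apertureRadius = 3.9, seed = 7L)
  # ~100 sites x ~47 px of shot-noise variance 100
  se <- sqrt(100 / (100 * 45))
  expect_lt(abs(est - 100), 3 * se + 0.2)
})

test_that("global background errors when the field is too crowded", {
  img <- matrix(100, 64, 64)
  grid <- expand.grid(x = seq(3, 60, by = 4), y = seq(3, 60, by = 4))
  expect_error(estimateBackgroundGlobal(img, grid, nSites = 100L,
    exclusionRadius = 15, apertureRadius = 3.9), "crowded")
})

test_that("the local annulus median tracks a linear background ramp", {
  ramp <- 100 + outer(rep(1, 64), 0:63) * 2   # 2 counts/px along x
  est <- estimateBackgroundLocal(ramp, x = 30, y = 30, innerRadius = 4,
                                 outerRadius = 8)
  expect_equal(est, 100 + 30 * 2, tolerance = 0.05 * 16)
  expect_true(is.na(estimateBackgroundLocal(ramp, 2, 30, 4, 8)))
})

test_that("local background correction is unbiased on fluorescence scenes", {
  sc <- simulateScene(SceneConfig(pixels = 256L, w = 80e-6,
    concentration = 8e-13, multiplicityFractions = 1,
    mode = "fluorescence", monomerMean = 6000, seed = 14L))
  loc <- detectClassical(sc$micrograph)
  sp <- measureIntensities(sc$micrograph, loc, backgroundMode = "local")
  m <- matchLocalizations(loc, sc$groundTruth, radius = 2)
  tru <- emitters(sc$groundTruth)$intensity[m$pairs[, "truth"]]
  est <- sp$corrected[m$pairs[, "detection"]]
  keep <- is.finite(est)
  resid <- (est[keep] - tru[keep]) / tru[keep]
  expect_lt(abs(mean(resid)), 0.05)
})

test_that("corrected intensities are invariant to a constant image offset", {
  sc <- smallScene(95L, pixels = 128L, w = 40e-6)
  loc <- detectClassical(sc$micrograph)
  img <- pixelData(sc$micrograph)
  for (mode in c("global", "local")) {
    a <- measureIntensities(img, loc, backgroundMode = mode, seed = 3L)
    b <- measureIntensities(img + 777, loc, backgroundMode = mode, seed = 3L)
    expect_equal(a$corrected, b$corrected, tolerance = 1e-9)
  }
})

test_that("a monomer-only simulation has its intensity mode at the monomer mean", {
  sc <- simulateScene(SceneConfig(pixels = 512L, w = 150e-6,
    concentration = 5e-13, multiplicityFractions = 1, seed = 17L))
  loc <- detectClassical(sc$micrograph)
  sp <- measureIntensities(sc$micrograph, loc)
  fit <- fitIntensityMixture(sp$corrected, K = 1)
  expect_equal(fit@mean, 2000, tolerance = 0.05)
})
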