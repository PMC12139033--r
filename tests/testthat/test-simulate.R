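test_that("zero concentration yields an empty scene of pure background", {
  sc <- simulateScene(SceneConfig(concentration = 0, pixels = 64L,
    w = 20e-6, seed = 1L))
  expect_identical(spotCount(sc$groundTruth), 0L)
  expect_identical(particleCount(sc$groundTruth), 0L)
  px <- pixelData(sc$micrograph)
  expect_equal(mean(px), 100, tolerance = 0.01)  # flat background only
})

test_that("the expected emitter count follows c * h * w^2 * N_A", {
  # 1.08 pmol/L in a 38 um x (300 um)^2 gel volume holds ~2231 particles;
  # monomers only, so emitters = particles
  cfg <- SceneConfig(concentration = 1.0825e-12, h = 38e-6, w = 300e-6,
    pixels = 512L, multiplicityFractions = 1, seed = 10L)
  expected <- 1.0825e-12 * 1e3 * 38e-6 * (300e-6)^2 * 6.02214076e23
  expect_equal(expected, 2231, tolerance = 2e-3)
  n <- spotCount(simulateScene(cfg)$groundTruth)
  expect_lt(abs(n - expected), 4 * sqrt(expected))  # Poisson draw
})

test_that("identical seeds give bit-identical scenes", {
  cfg <- SceneConfig(pixels = 64L, w = 20e-6, seed = 42L)
  a <- simulateScene(cfg)
  b <- simulateScene(cfg)
  expect_identical(pixelData(a$micrograph), pixelData(b$micrograph))
  expect_identical(emitters(a$groundTruth), emitters(b$groundTruth))
})

test_that("mean spot count over many scenes converges to the Poisson mean", {
  cfg0 <- SceneConfig(concentration = 1.8e-12, pixels = 64L, w = 20e-6)
  expSpots <- 1.8e-12 * 1e3 * 38e-6 * (20e-6)^2 * 6.02214076e23 /
    sum(1:3 * c(0.52, 0.30, 0.18))
  counts <- vapply(1:120, function(s)
    spotCount(simulateScene(SceneConfig(concentration = 1.8e-12,
      pixels = 64L, w = 20e-6, seed = s))$groundTruth), numeric(1))
  se <- sqrt(expSpots / 120)
  expect_lt(abs(mean(counts) - expSpots), 3 * se)
})

test_that("summed image flux matches background plus true intensities", {
  sc <- smallScene(77L)
  px <- pixelData(sc$micrograph)
  signal <- sum(px) - length(px) * 100
  em <- emitters(sc$groundTruth)
  # expected in-image flux: intensity times the PSF mass inside the frame
  n <- nrow(px); sig <- 1.3
  inFrame <- (pnorm((n - 0.5 - em$x) / sig) - pnorm((-0.5 - em$x) / sig)) *
             (pnorm((n - 0.5 - em$y) / sig) - pnorm((-0.5 - em$y) / sig))
  truth <- sum(em$intensity * inFrame)
  # shot noise of the total flux dominates the tolerance
  expect_lt(abs(signal - truth), 5 * sqrt(sum(px)) + 0.01 * truth)
})

test_that("fluorescence mode adds a smooth spatially varying background", {
  sc <- simulateScene(SceneConfig(concentration = 0, pixels = 128L,
    w = 40e-6, mode = "fluorescence", seed = 8L,
    backgroundCorrelation = 20))
  px <- pixelData(sc$micrograph)
  expect_gt(mean(px), 300)  # high background
  # smooth field: block means differ far beyond shot noise of a flat field
  blocks <- sapply(0:3, function(i)
    mean(px[, (i * 32 + 1):((i + 1) * 32)]))
  expect_gt(diff(range(blocks)), 10 * sqrt(400 / (128 * 32)))
})

test_that("overcrowded configurations are rejected", {
  cfg <- SceneConfig(concentration = 1e-9, pixels = 64L, w = 20e-6)
  expect_error(simulateScene(cfg), "sparse|overcrowded")
})

test_that("invalid scene configurations are rejected with a message", {
  expect_error(SceneConfig(multiplicityFractions = c(0.5, 0.4)), NA)
  # normalization happens in the constructor; direct slot abuse is caught
  cfg <- SceneConfig(pixels = 64L)
  cfg@multiplicityFractions <- c(0.5, 0.4)
  expect_error(validObject(cfg), "sum to 1")
  expect_error(SceneConfig(pixels = 32L), "pixels")
  expect_error(SceneConfig(h = -1), "positive")
})

test_that("scenes round-trip through TIFF and CSV exactly", {
  sc <- smallScene(5L)
  path <- file.path(tempdir(), "scene_rt.tif")
  writeScene(sc$micrograph, sc$groundTruth, path)
  back <- readScene(path)
  expect_identical(pixelData(back$micrograph), pixelData(sc$micrograph))
  expect_equal(fieldWidth(back$micrograph), fieldWidth(sc$micrograph))
  expect_equal(emitters(back$groundTruth)$intensity,
               emitters(sc$groundTruth)$intensity, tolerance = 1e-12)
  expect_identical(particleCount(back$groundTruth),
                   particleCount(sc$groundTruth))
})
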