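test_that("groups per particle is the concentration mole ratio", {
  expect_equal(groupsPerParticle(0.509e-3, 3.35e-9), 151940, tolerance = 1e-4)
  expect_equal(groupsPerParticle(20.84e-3, 551e-9), 37822, tolerance = 1e-4)
  expect_identical(groupsPerParticle(0, 1e-9), 0)
  expect_error(groupsPerParticle(1e-3, 0), "positive")
  # scale invariance of the mole ratio
  expect_equal(groupsPerParticle(0.509e-3 * 7, 3.35e-9 * 7),
               groupsPerParticle(0.509e-3, 3.35e-9))
})

test_that("surface density uses the sphere area pi * d^2", {
  expect_equal(surfaceDensity(151940, 66), 11.1, tolerance = 0.01)
  expect_equal(surfaceDensity(37822, 83), 1.75, tolerance = 0.01)
  expect_identical(surfaceDensity(0, 66), 0)
})

test_that("coating chain arithmetic matches the molar-mass ratios", {
  ch <- chainsPerParticle(151940, 1e5, 72)
  expect_identical(floor(ch$groupsPerChain), 1388)
  expect_equal(ch$chains, 109.4, tolerance = 0.005)
  expect_equal(chainsPerParticle(100, 72, 72)$groupsPerChain, 1)
})

test_that("bulk unit counts follow sphere volume, density and unit mass", {
  pn <- ParticleModel("polystyrene")
  expect_equal(bulkUnitsPerParticle(pn), 1.73e6, tolerance = 0.005)
  ucnp <- ParticleModel("ucnp")
  expect_equal(bulkUnitsPerParticle(ucnp), 1.86e6, tolerance = 0.01)
  expect_identical(bulkUnitsPerParticle(0, 1, 104), 0)
})

test_that("units per group round to the assay's structural ratios", {
  expect_equal(unitsPerGroup(1.7e6, 38e3), 44.7, tolerance = 0.005)
  expect_equal(unitsPerGroup(1.8e6, 151940), 11.85, tolerance = 0.005)
  expect_identical(unitsPerGroup(5, 5), 1)
})

test_that("runReport assembles the headline quantities coherently", {
  rep <- runReport(
    counting = list(mean = 3.35e-9, u = 0.27e-9),
    titration = list(mean = 0.509e-3, u = 0.019e-3),
    model = ParticleModel("ucnp"),
    nSamples = 2e5, seed = 4L)
  expect_equal(rep$values$groupsPerParticle, 151940, tolerance = 1e-4)
  expect_equal(rep$values$surfaceDensity, 11.1, tolerance = 0.01)
  expect_equal(rep$values$chainsPerParticle, 109.4, tolerance = 0.01)
  expect_equal(rep$values$unitsPerGroup,
               rep$values$bulkUnitsPerParticle / 151940, tolerance = 1e-4)
  # MC uncertainty close to the delta-method value at this sample size
  expect_equal(rep$values$groupsPerParticleU,
               deltaMethodRatioSD(0.509e-3, 0.019e-3, 3.35e-9, 0.27e-9),
               tolerance = 0.05)
  # JSON writing round-trips
  path <- file.path(tempdir(), "report_q.json")
  runReport(counting = list(mean = 3.35e-9, u = 0.27e-9),
    titration = list(mean = 0.509e-3, u = 0.019e-3),
    model = ParticleModel("ucnp"), nSamples = 1e5, seed = 4L, path = path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$values$groupsPerParticle, 151940, tolerance = 1e-4)
})

test_that("zeroed carboxyl input zeroes the derived metrics", {
  expect_identical(groupsPerParticle(0, 3.35e-9), 0)
  expect_identical(surfaceDensity(0, 66), 0)
})
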