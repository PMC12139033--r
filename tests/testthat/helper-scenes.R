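# Scene factories and a lazily trained, cached segmentation model shared by
# the detection tests.

# small field with the default pixel pitch (~0.3 um/px) and ~15 spots
smallScene <- function(seed, pixels = 64L, w = 20e-6,
    concentration = 1.8e-12, monomerMean = 4000, ...) {
  simulateScene(SceneConfig(concentration = concentration, w = w,
    pixels = as.integer(pixels), monomerMean = monomerMean, seed = seed, ...))
}

# sparse, bright, well-separated spots for detector scoring
highSnrScene <- function(seed, pixels = 256L) {
  simulateScene(SceneConfig(concentration = 3.9e-13, w = 75e-6,
    pixels = as.integer(pixels), monomerMean = 8000,
    multiplicityFractions = 1, seed = seed))
}

# first high-SNR scene at or after `seed` whose emitters are mutually
# well separated (pairwise distance >= 6 px); deterministic in `seed`
wellSeparatedScene <- function(seed) {
  repeat {
    sc <- highSnrScene(seed)
    em <- emitters(sc$groundTruth)
    d <- as.matrix(stats::dist(em[, c("x", "y")]))
    diag(d) <- Inf
    if (nrow(em) > 1L && min(d) >= 6) return(sc)
    seed <- seed + 1L
  }
}

.testCache <- new.env(parent = emptyenv())

trainedModel <- function() {
  if (is.null(.testCache$model)) {
    scenes <- lapply(1:50, smallScene)
    .testCache$model <- trainSpotNet(scenes, epochs = 25L, seed = 3L)
  }
  .testCache$model
}

# intensity sample drawn through the simulator's ground truth: pools true
# emitter intensities (and multiplicities) from as many scenes as needed
simulatedMixture <- function(n, seed, ...) {
  intensity <- numeric(0); multiplicity <- integer(0)
  s <- seed
  while (length(intensity) < n) {
    sc <- simulateScene(SceneConfig(seed = s, ...))
    em <- emitters(sc$groundTruth)
    intensity <- c(intensity, em$intensity)
    multiplicity <- c(multiplicity, em$multiplicity)
    s <- s + 1L
  }
  list(intensity = intensity[seq_len(n)],
       multiplicity = multiplicity[seq_len(n)])
}

simulatedIntensities <- function(n, seed, ...)
  simulatedMixture(n, seed, ...)$intensity
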