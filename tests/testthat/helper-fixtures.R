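# Shared fixtures, built once per session and memoised: small phantom
# cohorts and a trained desk-scale model reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

smallCohort <- function(n = 80L, size = 32L, noise = 0, seed = 42L) {
  memo(sprintf("cohort_%d_%d_%g_%d", n, size, noise, seed), {
    cfg <- phantomCohortConfig(nSubjects = n, imageSize = c(size, size),
                               noiseSd = noise, seed = seed)
    # tiny cohorts legitimately leave some age groups empty
    suppressWarnings(splitCohort(generateCohort(cfg), seed = seed + 1L))
  })
}

smallModel <- function() {
  memo("model_small", {
    co <- smallCohort(n = 120L)
    trainAgeModel(co, config = list(epochs = 6L, batchSize = 16L,
                                    seed = 7L))
  })
}

# an untrained tiny-cnn whose final feature map is 8x8 (32x32 input)
randomModel <- function(inputChannels = 1L, seed = 5L) {
  memo(sprintf("model_rand_%d_%d", inputChannels, seed), {
    bb <- tinyCnnBackbone(inputSize = c(32L, 32L),
                          inputChannels = inputChannels)
    new("AgeModel", backbone = bb,
        weights = ardaceph:::initWeights(bb, seed),
        inputChannels = inputChannels, config = list(),
        history = data.frame())
  })
}

randomNormalizedMaps <- function(n, size = 12L, seed = 1L, ages = NULL) {
  withSeed(seed, lapply(seq_len(n), function(i) {
    v <- matrix(runif(size * size), size, size)
    v <- (v - min(v)) / (max(v) - min(v))
    new("SalienceMap", values = v, id = sprintf("s%02d", i),
        age = if (is.null(ages)) runif(1, 4, 40) else ages[i],
        normalized = TRUE)
  }))
}
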