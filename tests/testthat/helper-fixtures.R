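# Shared fixtures: small generator configs and cached epoch sets so the
# slower end-to-end objects are built once per test run.

fixtureEnv <- new.env(parent = emptyenv())

# small paired dataset with moderate (default) effects, full montage
smallEpochs <- function() {
  if (is.null(fixtureEnv$smallEpochs)) {
    cfg <- generatorConfig(6, seed = 101)
    fixtureEnv$smallEpochs <- simulateEpochs(cfg)
  }
  fixtureEnv$smallEpochs
}

# ear-only epochs with strong effects for learnability checks
strongEarEpochs <- function(nSubjects = 8, seed = 202) {
  key <- sprintf("strong_%d_%d", nSubjects, seed)
  if (is.null(fixtureEnv[[key]])) {
    cfg <- generatorConfig(nSubjects, effects = strongEffectSizes(),
                          seed = seed)
    recs <- generatePairedDataset(cfg, channels = c("earL", "earR"))
    fixtureEnv[[key]] <- extractEpochs(lapply(recs, preprocessRecording))
  }
  fixtureEnv[[key]]
}

# deterministic sine-wave recording for filter tests
sineRecording <- function(freq, fs = 500, duration = 60, amp = 1) {
  tt <- seq(0, duration, by = 1 / fs)[seq_len(fs * duration)]
  EEGRecording(matrix(amp * sin(2 * pi * freq * tt), 1), fs = fs,
               channelLabels = "x", subjectId = "sine", condition = "relax")
}

rms <- function(x) sqrt(mean(x^2))

# random row-stochastic map
randomStochasticMap <- function(n) {
  m <- matrix(runif(n * n), n)
  m / rowSums(m)
}

# a tiny trained-ish model is unnecessary for most tests; a freshly built
# one suffices wherever only forward passes are exercised
freshModel <- function(variant = "full", seed = 7) {
  key <- sprintf("model_%s_%d", variant, seed)
  if (is.null(fixtureEnv[[key]]))
    fixtureEnv[[key]] <- buildVariant(modelConfig(), variant, seed = seed)
  fixtureEnv[[key]]
}
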