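smallSynth <- function(nTrialsPerClass = 8L, ...) {
  synthConfig(nTrialsPerClass = nTrialsPerClass, nClasses = 2L, nChannels = 6L,
              nSamples = 250L, fs = 250, ...)
}

test_that("generation is bit-identical for a fixed seed and balanced", {
  cfg <- smallSynth(seed = 11L)
  a <- generateSynthEEG(cfg)
  b <- generateSynthEEG(cfg)
  expect_identical(signals(a), signals(b))
  expect_identical(trialLabels(a), trialLabels(b))
  expect_equal(as.vector(table(trialLabels(a))), c(8, 8))
  # different session tag draws an independent stream
  cc <- generateSynthEEG(cfg, sessionTag = "test")
  expect_false(identical(signals(a), signals(cc)))
})

test_that("a carrier at or above Nyquist is rejected", {
  expect_error(smallSynth(classSignatures = list(
    list(channels = 1:2, freq = 125, depth = 0.5),
    list(channels = 3:4, freq = 20, depth = 0.5))), "Nyquist")
  expect_error(smallSynth(classSignatures = list(
    list(channels = 1:2, freq = 10, depth = 1.4),
    list(channels = 3:4, freq = 20, depth = 0.5))), "depth")
})

test_that("the band-power oracle separates the default fixture", {
  cfg <- synthConfig(seed = 1L)              # published geometry defaults
  tr <- generateSynthEEG(cfg, "S01", "train")
  te <- generateSynthEEG(cfg, "S01", "test")
  expect_gte(bandpowerOracle(tr, te), 0.9)
  # resubstitution on well-separated classes
  expect_gte(bandpowerOracle(tr, tr), 0.95)
})

test_that("zero modulation depth collapses the oracle to chance", {
  cfg <- withModulationDepth(synthConfig(seed = 2L), 0)
  cfg@nTrialsPerClass <- 25L
  tr <- generateSynthEEG(cfg, "S01", "train")
  teCfg <- cfg; teCfg@nTrialsPerClass <- 100L
  te <- generateSynthEEG(teCfg, "S01", "test")
  acc <- bandpowerOracle(tr, te)
  expect_lt(abs(acc - 0.25), 0.05)
})

test_that("label-shuffled training collapses the oracle to chance on average", {
  # With separable clusters a nearest-centroid rule under ONE permuted
  # labeling gives an arbitrary class-level outcome (the mixed centroids
  # differ only by noise, so whole classes fall on one side together); the
  # chance-level contract therefore holds for the mean over permutations.
  cfg <- synthConfig(nTrialsPerClass = 12L, nClasses = 4L, nChannels = 8L,
                     nSamples = 250L, fs = 250, seed = 5L)
  tr <- generateSynthEEG(cfg)
  te <- generateSynthEEG(cfg, sessionTag = "test")
  expect_gte(bandpowerOracle(tr, te), 0.9)   # intact labels: near perfect
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    tp <- tr
    tp@labels <- sample(tp@labels)
    bandpowerOracle(tp, te)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.25)    # chance up to class-level noise
  expect_lt(mean(accs), 0.6)                 # far below the intact accuracy
})

test_that("two classes differing only in 10 Hz power on one channel are separable", {
  sigs <- list(list(channels = 5L, freq = 10, depth = 0.9),
               list(channels = 5L, freq = 10, depth = 0))
  cfg <- synthConfig(nTrialsPerClass = 12L, nClasses = 2L, nChannels = 6L,
                     nSamples = 500L, fs = 250, classSignatures = sigs,
                     snr = 3, seed = 7L)
  tr <- generateSynthEEG(cfg)
  te <- generateSynthEEG(cfg, sessionTag = "test")
  expect_gte(bandpowerOracle(tr, te, bands = list(c(8, 12))), 0.9)
  expect_error(bandpowerOracle(tr, te, bands = list()), "non-empty")
})

test_that("oracle accuracy is non-decreasing in modulation depth", {
  depths <- c(0, 0.3, 0.6, 0.9)
  accs <- vapply(depths, function(d) {
    cfg <- withModulationDepth(smallSynth(seed = 13L, nTrialsPerClass = 16L), d)
    tr <- generateSynthEEG(cfg)
    te <- generateSynthEEG(cfg, sessionTag = "test")
    bandpowerOracle(tr, te)
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.05))      # monotone up to sampling error
  expect_gt(accs[4], accs[1])
})

test_that("the background spectrum follows the configured 1/f^alpha law", {
  cfg <- withModulationDepth(
    synthConfig(nTrialsPerClass = 6L, nClasses = 2L, nChannels = 4L,
                nSamples = 1000L, fs = 250, noiseExponent = 1, seed = 21L), 0)
  ts <- generateSynthEEG(cfg)
  expect_true(all(is.finite(signals(ts))))
  Tn <- nSamples(ts)
  freqs <- (0:(Tn - 1)) * samplingRate(ts) / Tn
  sel <- which(freqs >= 2 & freqs <= 40)
  pmean <- rep(0, length(sel))
  for (i in seq_len(nTrials(ts)))
    for (c in seq_len(nChannels(ts)))
      pmean <- pmean + (Mod(stats::fft(signals(ts)[i, c, ]))^2 / Tn)[sel]
  pmean <- pmean / (nTrials(ts) * nChannels(ts))
  slope <- stats::coef(stats::lm(log(pmean) ~ log(freqs[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.5)
})
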