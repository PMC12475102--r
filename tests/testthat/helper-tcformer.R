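# Shared fixtures: tiny geometries for unit/property tests, published-scale
# synthetic study for the end-to-end checks, and a session-level cache so the
# expensive training runs are performed once and reused across test files.

tcf <- asNamespace("tcformer")

tinyMkConfig <- function(dropout = 0.4) {
  mkConvConfig(kernels = c(5L, 8L), f1 = 4L, depthMultiplier = 2L,
               pool1 = 4L, pool2 = 2L, kernel2 = 3L, dGroup = 4L,
               seReduction = 2L, dropout = dropout)
}

tinyModelConfig <- function(variant = "C", nClasses = 3L, dropout = 0.4) {
  mk <- tinyMkConfig(dropout)
  modelConfig(nChannels = 3L, nSamples = 40L, nClasses = nClasses,
              variant = variant, mkconv = mk,
              encoder = encoderConfig(d = dModel(mk), dropout = dropout),
              tcn = tcnConfig())
}

# a fast 2-class learnable geometry for protocol smoke tests
protoSynthConfig <- function(nPerClass = 8L, seed = 3L, depth = 1) {
  synthConfig(nTrialsPerClass = nPerClass, nClasses = 2L, nChannels = 4L,
              nSamples = 56L, fs = 250,
              classSignatures = list(
                list(channels = 1:2, freq = 20, depth = depth),
                list(channels = 3:4, freq = 20, depth = depth)),
              snr = 3, seed = seed)
}

protoModelConfig <- function(variant = "A", nClasses = 2L) {
  mk <- mkConvConfig(kernels = c(8L, 12L), f1 = 4L, depthMultiplier = 2L,
                     pool1 = 8L, pool2 = 7L, kernel2 = 3L, dGroup = 4L,
                     seReduction = 2L, dropout = 0.2)
  modelConfig(nChannels = 4L, nSamples = 56L, nClasses = nClasses,
              variant = variant, mkconv = mk,
              encoder = encoderConfig(d = dModel(mk), dropout = 0.2),
              tcn = tcnConfig(dropout = 0.2))
}

makeTinyTrialSet <- function(n = 6L, C = 3L, Tn = 40L, nClasses = 3L,
                             seed = 1L, subjectId = "S1",
                             sessionTag = "train") {
  set.seed(seed)
  TrialSet(array(rnorm(n * C * Tn), c(n, C, Tn)),
           labels = rep(0:(nClasses - 1L), length.out = n),
           samplingRate = 250, subjectId = subjectId, sessionTag = sessionTag,
           nClasses = nClasses)
}

# ---- finite-difference utilities (double precision, R backend) --------------

leafPaths <- function(w, prefix = list()) {
  if (is.numeric(w)) return(list(prefix))
  keys <- if (!is.null(names(w)) && all(nzchar(names(w)))) names(w) else seq_along(w)
  out <- list()
  for (k in keys) out <- c(out, leafPaths(w[[k]], c(prefix, list(k))))
  out
}

getAt <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree }

setAt <- function(tree, path, val) {
  if (length(path) == 1) { tree[[path[[1]]]] <- val; return(tree) }
  tree[[path[[1]]]] <- setAt(tree[[path[[1]]]], path[-1], val)
  tree
}

# ---- session cache for the published-scale training runs --------------------

.smoke <- new.env(parent = emptyenv())

# the default synthetic fixture at the published geometry (4 classes, 22
# channels, 1000 samples at 250 Hz, modulation depth 0.8), standardized with
# training statistics
smokeData <- function(depth = 0.8) {
  key <- sprintf("data_%.2f", depth)
  if (!is.null(.smoke[[key]])) return(.smoke[[key]])
  cfg <- withModulationDepth(synthConfig(seed = 1L), depth)
  train <- generateSynthEEG(cfg, "S01", "train")
  teCfg <- cfg
  teCfg@nTrialsPerClass <- if (depth == 0) 75L else 25L
  test <- generateSynthEEG(teCfg, "S01", "test")
  stats <- computeChannelStats(train)
  out <- list(train = standardizeTrials(train, stats),
              test = standardizeTrials(test, stats))
  .smoke[[key]] <- out
  out
}

# one 60-epoch training run on the default fixture; cached per (variant, seed,
# depth)
smokeRun <- function(variant = "C", seed = 0L, depth = 0.8) {
  key <- sprintf("run_%s_%d_%.2f", variant, seed, depth)
  if (!is.null(.smoke[[key]])) return(.smoke[[key]])
  dat <- smokeData(depth)
  tcfg <- trainConfig(epochs = 60L, warmupEpochs = 20L, batchSize = 16L,
                      seed = seed)
  fit <- trainModel(buildModel(modelConfig(variant = variant), seed = seed),
                    dat$train, tcfg)
  pr <- tcfPredict(fit$model, dat$test)
  out <- list(model = fit$model, log = fit$log,
              testAcc = mean(pr$labels == trialLabels(dat$test)),
              trainAcc = utils::tail(fit$log$acc, 1))
  .smoke[[key]] <- out
  out
}

# run seeds until `needed` successes or seeds exhausted; returns accuracies
smokeSeedSweep <- function(variant, seeds, threshold, needed) {
  accs <- numeric(0)
  for (s in seeds) {
    accs <- c(accs, smokeRun(variant, s)$testAcc)
    if (sum(accs >= threshold) >= needed) break
  }
  accs
}
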