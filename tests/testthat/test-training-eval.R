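test_that("the schedule ramps linearly to the peak then cosine-decays to zero", {
  cfg <- trainConfig(epochs = 60L, warmupEpochs = 20L)
  expect_equal(lrAt(0, cfg), 0.0009 / 20)    # 0.000045
  expect_equal(lrAt(19, cfg), 0.0009)        # peak at the last warm-up epoch
  expect_lt(lrAt(59, cfg), 1e-6)             # cosine endpoint
  mids <- vapply(20:59, lrAt, numeric(1), config = cfg)
  expect_true(all(diff(mids) < 0))           # strictly decaying after warm-up
  expect_error(lrAt(60, cfg), "outside")
  expect_error(trainConfig(epochs = 10L, warmupEpochs = 10L), "warmup")
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(crossEntropy(matrix(c(100, 0, 0, 0), 1), 0L), 0, tolerance = 1e-6)
  expect_equal(crossEntropy(matrix(0, 2, 4), c(1L, 3L)), log(4))
  expect_equal(crossEntropy(matrix(c(2, 0), 1), 0L), log(1 + exp(-2)))  # 0.1269
  # stable under large logits
  expect_true(is.finite(crossEntropy(matrix(c(1e4, -1e4), 1), 0L)))
})

test_that("macro accuracy averages per-class recalls", {
  expect_equal(accuracyMacro(diag(c(5, 9, 2))), 1)
  expect_equal(accuracyMacro(matrix(c(8, 4, 2, 6), 2)), 0.7)  # (0.8 + 0.6)/2
  collapsed <- matrix(0L, 4, 4); collapsed[, 1] <- 10L
  expect_equal(accuracyMacro(collapsed), 0.25)
  expect_error(accuracyMacro(matrix(c(1, 0, 1, 0), 2)), "no samples")
})

test_that("macro accuracy equals plain accuracy on class-balanced test sets", {
  set.seed(1)
  for (rep in 1:10) {
    n <- 4L
    true <- rep(0:(n - 1L), each = 25)
    pred <- sample(0:(n - 1L), 100, replace = TRUE)
    cm <- confusionMatrix(true, pred, n)
    expect_equal(accuracyMacro(cm), mean(true == pred), tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches the closed form and an independent oracle", {
  expect_equal(cohensKappa(diag(c(10, 20, 5))), 1)
  expect_equal(cohensKappa(matrix(c(40, 20, 10, 30), 2)), 0.4)  # (0.7-0.5)/0.5
  # statistically independent predictions: product marginals -> kappa ~ 0
  ind <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(cohensKappa(ind), 0, tolerance = 1e-12)
  expect_equal(cohensKappa(matrix(c(7, 0, 0, 0), 2)), 0)  # degenerate marginals
  skip_if_not_installed("e1071")
  set.seed(2)
  for (rep in 1:10) {
    cm <- matrix(rpois(16, 8), 4)
    expect_equal(cohensKappa(cm), e1071::classAgreement(cm)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("paired t-test matches the closed form and its degenerate conventions", {
  r <- pairedTTest(c(5, 7, 9), c(3, 4, 5))   # differences 2, 3, 4
  expect_equal(r$t, 3 * sqrt(3), tolerance = 1e-10)       # 5.196
  expect_equal(r$p, 2 * pt(-3 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(r$df, 2)
  same <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  zero <- pairedTTest(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(zero$t, 0, tolerance = 1e-10)
  expect_equal(zero$p, 1, tolerance = 1e-10)
  const <- pairedTTest(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(const$t) && const$p == 0 && const$degenerate)
})

test_that("training is bit-reproducible for a fixed seed", {
  cfg <- tinyModelConfig("B")
  ts <- makeTinyTrialSet(n = 9, nClasses = 3L, seed = 20)
  tcfg <- trainConfig(epochs = 3L, warmupEpochs = 1L, batchSize = 4L, seed = 7L)
  f1 <- trainModel(buildModel(cfg, seed = 2), ts, tcfg)
  f2 <- trainModel(buildModel(cfg, seed = 2), ts, tcfg)
  expect_identical(f1$model@weights, f2$model@weights)
  expect_identical(f1$log, f2$log)
})

test_that("the first-epoch loss on balanced classes starts near ln(n_classes)", {
  run <- smokeRun("C", seed = 0L)            # 4 balanced classes
  expect_equal(run$log$loss[1], log(4), tolerance = 0.15)
  # and the fixed-epoch run reaches high training accuracy
  expect_gte(run$trainAcc, 0.95)
})

test_that("augmented training doubles the split and checks donor provenance", {
  cfg <- protoModelConfig("A")
  scfg <- protoSynthConfig()
  tr <- standardizeTrials(generateSynthEEG(scfg, "S1", "train"),
                          computeChannelStats(generateSynthEEG(scfg, "S1", "train")))
  tcfg <- trainConfig(epochs = 2L, warmupEpochs = 1L, batchSize = 8L,
                      seed = 1L, augment = TRUE)
  fit <- trainModel(buildModel(cfg, seed = 1), tr, tcfg)
  expect_s4_class(fit$model, "TCFormerModel")
  expect_equal(nrow(fit$log), 2)
})

test_that("a 9-subject study with 5 seeds yields exactly 45 within-subject results", {
  scfg <- protoSynthConfig(nPerClass = 4L)
  study <- makeSynthStudy(scfg, nSubjects = 9L, nTestPerClass = 4L)
  tcfg <- trainConfig(epochs = 2L, warmupEpochs = 1L, batchSize = 8L)
  res <- runWithinSubject(study, protoModelConfig("A"), tcfg, seeds = 0:4)
  expect_equal(nrow(res$results), 45)
  expect_equal(length(res$confusions), 45)
  expect_setequal(unique(res$results$subject), sprintf("S%02d", 1:9))
  expect_true(all(res$results$accuracy >= 0 & res$results$accuracy <= 1))
  expect_true(all(res$results$kappa >= -1 & res$results$kappa <= 1))
  # aggregation: identical accuracies give their value with zero SD, and the
  # aggregate is invariant to the ordering of rows
  agg <- aggregateResults(res$results)
  shuffled <- res$results[sample.int(45), ]
  agg2 <- aggregateResults(shuffled)
  expect_equal(agg, agg2)
  const <- data.frame(subject = rep(c("a", "b"), each = 2), seed = c(1, 2),
                      accuracy = 0.8, kappa = 0.6)
  aggc <- aggregateResults(const)
  expect_equal(unname(aggc$accuracy), c(0.8, 0))
})

test_that("session leakage is detected before any training happens", {
  scfg <- protoSynthConfig(nPerClass = 4L)
  tr <- generateSynthEEG(scfg, "S1", "train")
  leakyTest <- tr                            # same trial ids in both splits
  leakyTest@sessionTag <- "test"
  tcfg <- trainConfig(epochs = 2L, warmupEpochs = 1L, batchSize = 8L)
  expect_error(
    runWithinSubject(list(tr, leakyTest), protoModelConfig("A"), tcfg, seeds = 0L),
    "leakage")
})

test_that("LOSO rotates every subject out with provenance-checked pools", {
  scfg <- protoSynthConfig(nPerClass = 6L, depth = 1)
  study <- makeSynthStudy(scfg, nSubjects = 3L, nTestPerClass = 10L)
  tcfg <- trainConfig(epochs = 25L, warmupEpochs = 5L, batchSize = 8L)
  res <- runLOSO(study, protoModelConfig("B"), tcfg, seeds = 0L)
  expect_equal(nrow(res$results), 3)         # one fold per held-out subject
  expect_setequal(res$results$subject, sprintf("S%02d", 1:3))
  # shared class signatures across subjects make transfer learnable
  expect_gt(mean(res$results$accuracy), 0.5)
  expect_error(runLOSO(study[1:2], protoModelConfig("B"), tcfg),
               "fewer than two subjects")
})
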