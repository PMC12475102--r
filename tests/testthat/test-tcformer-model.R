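test_that("variants build with the expected heads and reproducible initialization", {
  cfg <- tinyModelConfig("A")
  mA <- buildModel(cfg, seed = 3)
  expect_null(mA@weights$encoder)            # no attention parameters
  expect_null(mA@weights$tcn)                # no dilated-conv parameters
  expect_false(is.null(mA@weights$dense))
  mA2 <- buildModel(cfg, seed = 3)
  expect_identical(mA@weights, mA2@weights)
  mA3 <- buildModel(cfg, seed = 4)
  expect_false(identical(mA@weights, mA3@weights))
  mB <- buildModel(tinyModelConfig("B"), seed = 3)
  expect_null(mB@weights$encoder)
  expect_length(mB@weights$tcn$classifier$W, 2)   # groups = n_groups
  mC <- buildModel(tinyModelConfig("C"), seed = 3)
  expect_length(mC@weights$tcn$classifier$W, 3)   # groups = n_groups + 1
  expect_error(modelConfig(encoder = encoderConfig(d = 24L)), "d_model")
})

test_that("forward pass emits one logit row per trial at the published geometry", {
  m <- buildModel(modelConfig(variant = "C"), seed = 0)
  set.seed(1)
  x <- array(rnorm(2 * 22 * 1000), c(2, 22, 1000))
  pr <- tcfPredict(m, x)
  expect_equal(dim(pr$logits), c(2, 4))
  expect_equal(rowSums(pr$probs), c(1, 1), tolerance = 1e-6)
  expect_identical(pr$logits, tcfPredict(m, x)$logits)   # eval determinism
})

test_that("prediction breaks ties toward the lowest class and refuses train mode", {
  cfg <- tinyModelConfig("C", nClasses = 4L)
  m <- buildModel(cfg, seed = 1)
  # zero classifier -> all logits equal -> everything argmaxes to class 0
  m@weights$tcn$classifier$W <- lapply(m@weights$tcn$classifier$W, function(w) w * 0)
  m@weights$tcn$classifier$b <- lapply(m@weights$tcn$classifier$b, function(b) b * 0)
  set.seed(2)
  x <- array(rnorm(3 * 3 * 40), c(3, 3, 40))
  pr <- tcfPredict(m, x)
  expect_true(all(pr$logits == 0))
  expect_equal(pr$labels, rep(0L, 3))
  expect_equal(rowSums(pr$probs), rep(1, 3), tolerance = 1e-9)
  expect_error(tcfPredict(m, x, mode = "train"), "eval")
  # plain argmax on distinct logits
  expect_equal(max.col(matrix(c(1, 3, 2, -1), 1), ties.method = "first") - 1L, 1L)
})

test_that("parameter audits reproduce the published budgets", {
  sA <- countParameters(buildModel(modelConfig(variant = "A"), seed = 0))
  sB <- countParameters(buildModel(modelConfig(variant = "B"), seed = 0))
  sC <- countParameters(buildModel(modelConfig(variant = "C"), seed = 0))
  expect_equal(roundK(sA@total), 27.5)
  expect_equal(roundK(sB@total), 37.3)
  expect_equal(roundK(sC@total), 77.8)
  expect_equal(sC@total, sum(sC@perStage))   # total equals the sum of parts
  expect_equal(unname(sC@detail$mkconv["grouped_se"]), 207)  # ~0.2k SE cost
  expect_output(show(sC), "77.8k")
})

test_that("full-model analytic gradients match finite differences (all variants)", {
  withr::local_options(tcformer.backend = "R")
  for (variant in c("A", "B", "C")) {
    cfg <- tinyModelConfig(variant)
    model <- buildModel(cfg, seed = 1)
    B <- 3L
    set.seed(5)
    x <- matrix(rnorm(40 * 3 * B), 40, 3 * B)
    y <- c(0L, 2L, 1L)
    lossAt <- function(w) {
      m2 <- model; m2@weights <- w
      set.seed(11)                           # identical dropout / drop-path draws
      fw <- tcf$modelFwd(m2, x, B, train = TRUE)
      tcf$ceLossFwd(fw$logits, y)$loss
    }
    set.seed(11)
    fw <- tcf$modelFwd(model, x, B, train = TRUE)
    ce <- tcf$ceLossFwd(fw$logits, y)
    g <- tcf$modelBwd(model, fw$caches, tcf$ceLossBwd(ce$cache))
    paths <- leafPaths(model@weights)
    set.seed(77)
    for (pi in sample(length(paths), 15)) {
      p <- paths[[pi]]
      leaf <- getAt(model@weights, p)
      idx <- sample(length(leaf), 1)
      eps <- 1e-5
      lp <- leaf; lp[idx] <- lp[idx] + eps
      lm <- leaf; lm[idx] <- lm[idx] - eps
      num <- (lossAt(setAt(model@weights, p, lp)) -
              lossAt(setAt(model@weights, p, lm))) / (2 * eps)
      ana <- getAt(g, p)[idx]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = sprintf("variant %s d/d %s[%d] (analytic)", variant,
                                   paste(unlist(p), collapse = "/"), idx))
    }
  }
})

test_that("relabeling classes with a matching classifier permutation permutes the confusion matrix exactly", {
  cfg <- protoModelConfig("B", nClasses = 2L)
  scfg <- protoSynthConfig(nPerClass = 8L)
  tr <- generateSynthEEG(scfg, "S1", "train")
  te <- generateSynthEEG(scfg, "S1", "test")
  st <- computeChannelStats(tr)
  trs <- standardizeTrials(tr, st); tes <- standardizeTrials(te, st)
  tcfg <- trainConfig(epochs = 6L, warmupEpochs = 2L, batchSize = 8L, seed = 0L)

  perm <- c(2L, 1L)                          # swap the two classes
  m1 <- buildModel(cfg, seed = 0)
  m2 <- m1
  m2@weights$tcn$classifier$W <- lapply(m1@weights$tcn$classifier$W,
                                        function(w) w[, perm, drop = FALSE])
  m2@weights$tcn$classifier$b <- lapply(m1@weights$tcn$classifier$b,
                                        function(b) b[perm])
  relabel <- function(ts) { ts@labels <- perm[ts@labels + 1L] - 1L; ts }

  f1 <- trainModel(m1, trs, tcfg)
  f2 <- trainModel(m2, relabel(trs), tcfg)
  cm1 <- confusionMatrix(trialLabels(tes), tcfPredict(f1$model, tes)$labels, 2L)
  cm2 <- confusionMatrix(perm[trialLabels(tes) + 1L] - 1L,
                         tcfPredict(f2$model, tes)$labels, 2L)
  expect_equal(unname(cm2), unname(cm1[perm, perm]))
})

test_that("variant C learns the default synthetic fixture and variant A follows", {
  # 60-epoch runs on the published geometry, shared with the acceptance suite
  accsC <- smokeSeedSweep("C", seeds = 0:2, threshold = 0.90, needed = 2)
  expect_gte(sum(accsC >= 0.90), 2)
  accsA <- smokeSeedSweep("A", seeds = 0:2, threshold = 0.80, needed = 2)
  expect_gte(sum(accsA >= 0.80), 2)
})
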