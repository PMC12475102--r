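#' Training configuration
#'
#' Fixed-epoch Adam training (beta1 = 0.9, beta2 = 0.999, no weight decay)
#' with a linear warm-up over the first `warmupEpochs` epochs followed by
#' cosine decay to zero, seeded shuffling, and optional
#' segmentation-and-reconstruction augmentation of the training split. There
#' is no early stopping and no model selection: the final-epoch weights are
#' evaluated. Published protocol values: 1000 epochs within-subject (500 for
#' the two-class benchmark), 125/77 epochs for the cross-subject protocols,
#' peak learning rate 0.0009, 20 warm-up epochs within-subject (3 for LOSO).
#'
#' @param epochs number of training epochs.
#' @param peakLr peak learning rate (default 9e-4).
#' @param warmupEpochs linear warm-up length.
#' @param batchSize minibatch size (default 64).
#' @param seed run seed; drives shuffling, dropout, stochastic depth and
#'   augmentation.
#' @param augment apply S&R augmentation with `m_A = m` (doubling)?
#' @param augSegments number of S&R fragments N_s.
#' @return a `TrainConfig`.
#' @aliases TrainConfig-class
#' @exportClass TrainConfig
#' @export
trainConfig <- function(epochs = 1000L, peakLr = 9e-4, warmupEpochs = 20L,
                        batchSize = 64L, seed = 0L, augment = FALSE,
                        augSegments = 8L) {
  new("TrainConfig", epochs = as.integer(epochs), peakLr = peakLr,
      warmupEpochs = as.integer(warmupEpochs), batchSize = as.integer(batchSize),
      seed = as.integer(seed), augment = augment,
      augSegments = as.integer(augSegments))
}

setClass("TrainConfig", representation(
  epochs = "integer", peakLr = "numeric", warmupEpochs = "integer",
  batchSize = "integer", seed = "integer", augment = "logical",
  augSegments = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@warmupEpochs >= object@epochs) return("warmupEpochs must be < epochs")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  TRUE
})

#' Learning rate at a given epoch
#'
#' Linear ramp `(epoch + 1) / warmup * peak` during warm-up (the peak is
#' reached at the last warm-up epoch), then cosine decay from the peak to 0 at
#' the final epoch.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param config a [trainConfig()].
#' @return the learning rate.
#' @export
lrAt <- function(epoch, config) {
  if (epoch < 0 || epoch >= config@epochs)
    stop(sprintf("epoch %d outside [0, %d)", epoch, config@epochs))
  wu <- config@warmupEpochs
  if (epoch < wu) return((epoch + 1) / wu * config@peakLr)
  denom <- max(1L, config@epochs - 1L - wu)
  config@peakLr * 0.5 * (1 + cos(pi * (epoch - wu) / denom))
}

#' Cross-entropy loss
#'
#' Mean negative log softmax probability of the true class,
#' `L = -(1/M) sum_i log p_i[y_i]`, computed with log-sum-exp stabilization.
#'
#' @param logits `B x n_classes` matrix.
#' @param labels 0-based integer labels.
#' @return scalar loss.
#' @export
crossEntropy <- function(logits, labels) ceLossFwd(logits, labels)$loss

#' Confusion matrix from true and predicted labels
#'
#' @param true,pred 0-based integer label vectors.
#' @param n number of classes.
#' @return `n x n` integer matrix, rows = true class, columns = predicted.
#' @export
confusionMatrix <- function(true, pred, n) {
  cm <- matrix(0L, n, n)
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  dimnames(cm) <- list(true = 0:(n - 1), predicted = 0:(n - 1))
  cm
}

#' Macro-averaged accuracy
#'
#' `ACC = (1/n) sum_i TP_i / I_i`: the unweighted mean of per-class recalls.
#' Equals plain accuracy when the test set is exactly class-balanced.
#'
#' @param cm confusion matrix (rows = true class).
#' @return accuracy in `[0, 1]`.
#' @export
accuracyMacro <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("macro accuracy undefined: a true class has no samples")
  mean(diag(as.matrix(cm)) / rs)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(P_a - P_e) / (1 - P_e)` with observed
#' agreement `P_a` the pooled diagonal fraction and expected agreement `P_e`
#' from the marginal products. Degenerate marginals (`P_e = 1`) return 0.
#'
#' @param cm confusion matrix (rows = true class).
#' @return kappa in `[-1, 1]`.
#' @export
cohensKappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

#' Two-tailed paired t-test on subject-level accuracy means
#'
#' Standard paired t statistic with `n - 1` degrees of freedom. Conventions
#' for degenerate inputs: all-zero differences give `p = 1` (`t = 0`);
#' zero-variance nonzero differences give `p = 0` with an infinite statistic
#' (flagged).
#'
#' @param a,b equal-length numeric vectors (length >= 2), e.g. per-subject
#'   accuracy means of two models.
#' @return list with `t`, `p`, `df` and `degenerate`.
#' @export
pairedTTest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1L, degenerate = TRUE))
  if (stats::sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L, degenerate = TRUE))
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       degenerate = FALSE)
}

# ---- Adam over nested weight lists -------------------------------------------

zeroLike <- function(w) {
  if (is.numeric(w)) return(w * 0)
  lapply(w, zeroLike)
}

# recursive Adam step over parallel weight/grad/moment trees
adamStep <- function(w, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.numeric(w)) {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    mhat <- m2 / (1 - b1^t)
    vhat <- v2 / (1 - b2^t)
    return(list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2))
  }
  keys <- if (!is.null(names(w))) names(w) else seq_along(w)
  for (k in keys) {
    r <- adamStep(w[[k]], g[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps)
    w[[k]] <- r$w; m[[k]] <- r$m; v[[k]] <- r$v
  }
  list(w = w, m = m, v = v)
}

# donor provenance check: every augmentation donor must be a training trial
assertAugProvenance <- function(train) {
  md <- train@metadata
  if (is.null(md$donors)) return(invisible(TRUE))
  ids <- trialIds(train)[!md$augmented]
  if (!all(md$donor_ids %in% ids))
    stop("augmentation donors come from outside the training split")
  invisible(TRUE)
}

#' Train a model for a fixed number of epochs
#'
#' Minibatch Adam with the [lrAt()] schedule and seeded shuffling; the
#' final-epoch weights are returned (no early stopping, no model selection).
#' When `config@augment` is set, the training split is doubled by
#' [segmentAndReconstruct()] before the first epoch; donor provenance is
#' verified so augmented fragments can never originate outside the training
#' split. The caller is responsible for standardizing with training-split
#' statistics (the protocol drivers do this).
#'
#' @param model a freshly built [TCFormerModel-class].
#' @param train a (standardized) training [TrialSet-class].
#' @param config a [trainConfig()].
#' @return list with the trained `model` and a per-epoch `log` data frame
#'   (epoch, lr, train loss, train accuracy).
#' @export
trainModel <- function(model, train, config) {
  stopifnot(is(model, "TCFormerModel"), is(train, "TrialSet"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config@seed)

  if (config@augment) {
    plan <- augmentationPlan(nSegments = config@augSegments,
                             nAugmented = nTrials(train), seed = config@seed + 1L)
    train <- segmentAndReconstruct(train, plan)
  }
  assertAugProvenance(train)

  n <- nTrials(train)
  labs <- trialLabels(train)
  x_all <- signals(train)
  m <- zeroLike(model@weights); v <- zeroLike(model@weights)
  logRows <- vector("list", config@epochs)
  t_step <- 0L
  for (epoch in 0:(config@epochs - 1L)) {
    lr <- lrAt(epoch, config)
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0
    for (i0 in seq(1L, n, by = config@batchSize)) {
      idx <- ord[i0:min(n, i0 + config@batchSize - 1L)]
      xb <- batchToMat(x_all[idx, , , drop = FALSE])
      yb <- labs[idx]
      fw <- modelFwd(model, xb, length(idx), train = TRUE)
      model@buffers <- fw$buffers
      ce <- ceLossFwd(fw$logits, yb)
      tot_loss <- tot_loss + ce$loss * length(idx)
      tot_correct <- tot_correct +
        sum(max.col(fw$logits, ties.method = "first") - 1L == yb)
      grads <- modelBwd(model, fw$caches, ceLossBwd(ce$cache))
      t_step <- t_step + 1L
      upd <- adamStep(model@weights, grads, m, v, lr, t_step)
      model@weights <- upd$w; m <- upd$m; v <- upd$v
    }
    logRows[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, loss = tot_loss / n, acc = tot_correct / n)
  }
  list(model = model, log = do.call(rbind, logRows))
}

# ---- evaluation protocols ----------------------------------------------------

evalOn <- function(model, test) {
  pr <- tcfPredict(model, test)
  cm <- confusionMatrix(trialLabels(test), pr$labels, nClasses(test))
  list(accuracy = accuracyMacro(cm), kappa = cohensKappa(cm), confusion = cm)
}

assertNoLeak <- function(train, test) {
  common <- intersect(trialIds(train), trialIds(test))
  if (length(common))
    stop("session leakage: test trials found in the training split: ",
         paste(utils::head(common, 3), collapse = ", "))
  invisible(TRUE)
}

combineTrials <- function(sets) {
  stopifnot(length(sets) >= 1)
  C <- nChannels(sets[[1]]); Tn <- nSamples(sets[[1]])
  for (s in sets) stopifnot(nChannels(s) == C, nSamples(s) == Tn)
  n <- sum(vapply(sets, nTrials, integer(1)))
  x <- array(0, c(n, C, Tn))
  labs <- integer(0); ids <- character(0)
  at <- 0L
  for (s in sets) {
    k <- nTrials(s)
    if (k) x[at + seq_len(k), , ] <- signals(s)
    labs <- c(labs, trialLabels(s)); ids <- c(ids, trialIds(s))
    at <- at + k
  }
  TrialSet(x, labs, samplingRate(sets[[1]]),
           channelNames = channelNames(sets[[1]]), subjectId = "pooled",
           sessionTag = sessionTag(sets[[1]]),
           nClasses = max(vapply(sets, nClasses, integer(1))), trialIds = ids)
}

runOne <- function(modelCfg, trainCfg, trainSet, testSet, subject, seed, mode,
                   logDir = NULL) {
  assertNoLeak(trainSet, testSet)
  stats <- computeChannelStats(trainSet)
  trs <- standardizeTrials(trainSet, stats)
  tes <- standardizeTrials(testSet, stats)
  cfg <- trainCfg; cfg@seed <- as.integer(seed)
  model <- buildModel(modelCfg, seed = seed)
  fit <- trainModel(model, trs, cfg)
  ev <- evalOn(fit$model, tes)
  logPath <- NA_character_
  if (!is.null(logDir)) {
    dir.create(logDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(logDir, sprintf("%s_%s_seed%d.csv", mode, subject, seed))
    utils::write.csv(fit$log, logPath, row.names = FALSE)
  }
  list(row = data.frame(subject = subject, seed = seed, mode = mode,
                        accuracy = ev$accuracy, kappa = ev$kappa,
                        logPath = logPath, stringsAsFactors = FALSE),
       confusion = ev$confusion, log = fit$log)
}

splitStudy <- function(dataset) {
  subj <- vapply(dataset, subjectId, character(1))
  sess <- vapply(dataset, sessionTag, character(1))
  list(subjects = unique(subj), subj = subj, sess = sess)
}

#' Within-subject evaluation protocol
#'
#' One model per (subject, seed): trained on the subject's training session,
#' evaluated on the held-out session of the same subject. Standardization
#' statistics come from the training session only; any id overlap between the
#' two sessions is an error.
#'
#' @param dataset list of [TrialSet-class] objects, one per
#'   (subject, session), with `sessionTag` `"train"` / `"test"`.
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @param seeds integer run seeds (default `0:(nSeeds-1)` style vectors).
#' @param logDir optional directory for per-run per-epoch CSV training logs
#'   (epoch, lr, train loss, train accuracy); paths are recorded in the
#'   results.
#' @return list with `results` (one row per subject x seed) and `confusions`.
#' @export
runWithinSubject <- function(dataset, modelCfg, trainCfg, seeds = 0:4,
                             logDir = NULL) {
  st <- splitStudy(dataset)
  rows <- list(); confs <- list()
  for (s in st$subjects) {
    tr <- dataset[st$subj == s & st$sess == "train"]
    te <- dataset[st$subj == s & st$sess == "test"]
    if (length(tr) != 1L || length(te) != 1L)
      stop("subject ", s, " must have exactly one train and one test session")
    for (seed in seeds) {
      r <- runOne(modelCfg, trainCfg, tr[[1]], te[[1]], s, seed, "within", logDir)
      rows[[length(rows) + 1L]] <- r$row
      confs[[sprintf("%s:%d", s, seed)]] <- r$confusion
    }
  }
  list(results = do.call(rbind, rows), confusions = confs)
}

#' Leave-one-subject-out evaluation protocol
#'
#' For each held-out subject: train on the pooled training sessions of all
#' other subjects, evaluate on the held-out subject's test session, rotating
#' over all subjects. Standardization statistics come from the pooled
#' training portion. The held-out subject's data never enter the training
#' pool (enforced by trial-id provenance).
#'
#' @inheritParams runWithinSubject
#' @return list with `results` and `confusions`.
#' @export
runLOSO <- function(dataset, modelCfg, trainCfg, seeds = 0L, logDir = NULL) {
  st <- splitStudy(dataset)
  if (length(st$subjects) < 2L)
    stop("LOSO is undefined with fewer than two subjects")
  rows <- list(); confs <- list()
  for (s in st$subjects) {
    pool <- dataset[st$subj != s & st$sess == "train"]
    te <- dataset[st$subj == s & st$sess == "test"]
    if (length(te) != 1L) stop("subject ", s, " must have exactly one test session")
    trainSet <- combineTrials(pool)
    if (any(grepl(paste0("^", s, ":"), trialIds(trainSet))))
      stop("held-out subject's data found in the LOSO training pool")
    for (seed in seeds) {
      r <- runOne(modelCfg, trainCfg, trainSet, te[[1]], s, seed, "loso", logDir)
      rows[[length(rows) + 1L]] <- r$row
      confs[[sprintf("%s:%d", s, seed)]] <- r$confusion
    }
  }
  list(results = do.call(rbind, rows), confusions = confs)
}

#' Aggregate per-run results to the reported mean +- SD
#'
#' Per-subject mean over seeds first, then mean and standard deviation across
#' subjects; invariant to the ordering of the result rows.
#'
#' @param results data frame from [runWithinSubject()] / [runLOSO()].
#' @return list with `perSubject` (data frame) and `accuracy` / `kappa`
#'   (each `c(mean, sd)`).
#' @export
aggregateResults <- function(results) {
  subj <- sort(unique(results$subject))
  per <- do.call(rbind, lapply(subj, function(s) {
    r <- results[results$subject == s, ]
    data.frame(subject = s, accuracy = mean(r$accuracy), kappa = mean(r$kappa))
  }))
  list(perSubject = per,
       accuracy = c(mean = mean(per$accuracy),
                    sd = if (nrow(per) > 1) stats::sd(per$accuracy) else 0),
       kappa = c(mean = mean(per$kappa),
                 sd = if (nrow(per) > 1) stats::sd(per$kappa) else 0))
}
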