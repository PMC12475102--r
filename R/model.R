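#' TCFormer model object
#'
#' Holds the configuration, all trainable weights and the batch-norm running
#' statistics of one decoder instance. Build with [buildModel()].
#'
#' @slot config a [modelConfig()].
#' @slot weights nested list of numeric arrays (trainable).
#' @slot buffers nested list of batch-norm running statistics (not trainable).
#' @aliases TCFormerModel-class
#' @exportClass TCFormerModel
setClass("TCFormerModel", representation(
  config = "ModelConfig", weights = "list", buffers = "list"))

setMethod("show", "TCFormerModel", function(object) {
  cfg <- object@config
  s <- countParameters(object)
  cat(sprintf("TCFormer variant %s: C=%d, T=%d, %d classes\n",
              cfg@variant, cfg@nChannels, cfg@nSamples, cfg@nClasses))
  cat(sprintf("  tokens T_c=%d, TCN receptive field %d, %s trainable parameters (%.1fk)\n",
              s@tokenCount, s@rfs, format(s@total, big.mark = ","), s@total / 1000))
  invisible(NULL)
})

#' Build a TCFormer model (or an ablation variant)
#'
#' Variant `"A"` is the conv front-end with a dense classifier on the
#' flattened tokens; `"B"` adds the grouped TCN head (groups = n_groups)
#' instead; `"C"` is the full decoder: front-end, grouped-query Transformer
#' encoder, fusion of encoder and conv tokens, TCN head with groups =
#' n_groups + 1, and per-group classifiers. Weights are drawn fan-in uniform
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`) from a generator seeded by `seed`;
#' batch-norm scale/shift start at 1/0.
#'
#' @param config a [modelConfig()].
#' @param seed integer seed fixing the initialization.
#' @return a [TCFormerModel-class].
#' @export
buildModel <- function(config, seed = 0L) {
  validObject(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  mk <- config@mkconv
  Tc <- tokenCount(config@nSamples, mk@pool1, mk@pool2)
  w <- list(mkconv = mkconvInit(mk, config@nChannels))
  b <- list(mkconv = mkconvBuffers(mk))
  dm <- dModel(mk)
  if (config@variant == "C") {
    w$encoder <- encoderInit(config@encoder)
    u <- function(n, fanin) stats::runif(n, -1 / sqrt(fanin), 1 / sqrt(fanin))
    w$fusion <- list(W = matrix(u(dm * mk@dGroup, dm), dm, mk@dGroup),
                     b = u(mk@dGroup, dm))
  }
  if (config@variant == "A") {
    u <- function(n, fanin) stats::runif(n, -1 / sqrt(fanin), 1 / sqrt(fanin))
    flat <- Tc * dm
    w$dense <- list(W = matrix(u(flat * config@nClasses, flat), flat, config@nClasses),
                    b = u(config@nClasses, flat))
  } else {
    dF <- fusedDim(config)
    grp <- tcnGroups(config)
    w$tcn <- tcnInit(config@tcn, dF, grp, config@nClasses)
    b$tcn <- tcnBuffers(config@tcn, dF)
    if (Tc > receptiveField(config@tcn@kernel, config@tcn@nBlocks))
      warning(sprintf("T_c = %d exceeds the TCN receptive field %d; the last step cannot see the whole sequence",
                      Tc, receptiveField(config@tcn@kernel, config@tcn@nBlocks)))
  }
  new("TCFormerModel", config = config, weights = w, buffers = b)
}

# ---- full forward / backward -------------------------------------------------

# x: (T x C*B) matrix; returns logits and, in train mode, all caches
modelFwd <- function(model, x, B, train) {
  cfg <- model@config
  mk <- cfg@mkconv
  dm <- dModel(mk)
  w <- model@weights; buf <- model@buffers
  r <- mkconvFwd(x, w$mkconv, buf$mkconv, mk, cfg@nChannels, B, train)
  buf$mkconv <- r$buffers
  Tc <- r$Tc
  caches <- list(mk = r$caches, Tc = Tc, B = B)
  Z <- r$out
  if (cfg@variant == "A") {
    flat <- matrix(aperm(array(Z, c(Tc, B, dm)), c(2, 1, 3)), B, Tc * dm)
    li <- linFwd(flat, w$dense$W, w$dense$b)
    caches$dense <- li$cache
    logits <- li$out
  } else {
    if (cfg@variant == "C") {
      enc <- encFwd(Z, w$encoder, cfg@encoder, Tc, B, train)
      caches$enc <- enc$caches
      proj <- linFwd(enc$out, w$fusion$W, w$fusion$b)
      caches$fusion <- proj$cache
      Fm <- cbind(Z, proj$out)
    } else Fm <- Z
    tr <- tcnTrunkFwd(Fm, w$tcn, buf$tcn, cfg@tcn, Tc, B, tcnGroups(cfg), train)
    buf$tcn <- tr$buffers
    caches$tcn <- tr$caches
    h <- tr$out[lastTokenRows(Tc, B), , drop = FALSE]
    cl <- classifierFwd(h, w$tcn$classifier)
    caches$cls <- cl$cache
    logits <- cl$out
  }
  list(logits = logits, caches = caches, buffers = buf)
}

modelBwd <- function(model, caches, dlogits) {
  cfg <- model@config
  mk <- cfg@mkconv
  dm <- dModel(mk)
  Tc <- caches$Tc; B <- caches$B
  g <- list()
  if (cfg@variant == "A") {
    li <- linBwd(caches$dense, dlogits)
    g$dense <- list(W = li$dW, b = li$db)
    dZ <- matrix(aperm(array(li$dx, c(B, Tc, dm)), c(2, 1, 3)), Tc * B, dm)
  } else {
    cl <- classifierBwd(caches$cls, dlogits)
    dSeq <- matrix(0, Tc * B, ncol(cl$dh))
    dSeq[lastTokenRows(Tc, B), ] <- cl$dh
    tb <- tcnTrunkBwd(caches$tcn, cfg@tcn, dSeq)
    g$tcn <- list(blocks = tb$grads, classifier = list(W = cl$dW, b = cl$db))
    if (cfg@variant == "C") {
      dZ <- tb$dx[, seq_len(dm), drop = FALSE]
      dproj <- tb$dx[, dm + seq_len(mk@dGroup), drop = FALSE]
      fu <- linBwd(caches$fusion, dproj)
      g$fusion <- list(W = fu$dW, b = fu$db)
      eb <- encBwd(caches$enc, model@weights$encoder, cfg@encoder, fu$dx)
      dZ <- dZ + eb$dZ
      eb$dZ <- NULL
      g$encoder <- eb
    } else dZ <- tb$dx
  }
  g$mkconv <- mkconvBwd(caches$mk, dZ)
  g
}

# ---- parameter audit ---------------------------------------------------------

countLeaves <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (is.list(x)) return(sum(vapply(x, countLeaves, numeric(1))))
  0
}

#' Parameter-count summary
#'
#' Exact count of trainable scalars per stage (batch-norm running statistics
#' excluded), the token count and the TCN receptive field. The `show` method
#' prints the per-stage breakdown with counts rounded half-up to 0.1k, the
#' convention used when quoting budgets like "77.8k".
#'
#' @param model a [TCFormerModel-class].
#' @return a `ModelSummary`.
#' @aliases ModelSummary-class
#' @exportClass ModelSummary
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "TCFormerModel"))
  cfg <- model@config
  w <- model@weights
  mkc <- w$mkconv
  mkDetail <- c(
    temporal_conv = countLeaves(mkc$Wt),
    batch_norms = countLeaves(list(mkc$bn1, mkc$bn2, mkc$bn3, mkc$bn4)),
    grouped_se = countLeaves(mkc$se),
    depthwise_spatial = countLeaves(mkc$Wd),
    pointwise_reduction = countLeaves(mkc$reduce),
    second_temporal_conv = countLeaves(mkc$conv2))
  perStage <- c(mkconv = sum(mkDetail))
  detail <- list(mkconv = mkDetail)
  if (!is.null(w$encoder)) {
    encDetail <- c(input_mixing = countLeaves(w$encoder$mix))
    for (i in seq_along(w$encoder$layers)) {
      ly <- w$encoder$layers[[i]]
      encDetail[sprintf("layer%d_attention", i)] <-
        countLeaves(list(ly$ln1, ly$Wq, ly$Wk, ly$Wv, ly$Wo))
      encDetail[sprintf("layer%d_ffn", i)] <-
        countLeaves(list(ly$ln2, ly$W1, ly$b1, ly$W2, ly$b2))
    }
    perStage["encoder"] <- sum(encDetail)
    detail$encoder <- encDetail
  }
  if (!is.null(w$fusion)) {
    perStage["fusion"] <- countLeaves(w$fusion)
    detail$fusion <- c(projection = countLeaves(w$fusion))
  }
  if (!is.null(w$tcn)) {
    tcnDetail <- vapply(seq_along(w$tcn$blocks), function(bk)
      countLeaves(w$tcn$blocks[[bk]]), numeric(1))
    names(tcnDetail) <- sprintf("block%d", seq_along(w$tcn$blocks))
    perStage["tcn"] <- sum(tcnDetail)
    detail$tcn <- tcnDetail
    perStage["classifier"] <- countLeaves(w$tcn$classifier)
    detail$classifier <- c(per_group = countLeaves(w$tcn$classifier))
  }
  if (!is.null(w$dense)) {
    perStage["classifier"] <- countLeaves(w$dense)
    detail$classifier <- c(dense = countLeaves(w$dense))
  }
  new("ModelSummary",
      perStage = perStage, detail = detail, total = sum(perStage),
      tokenCount = tokenCount(cfg@nSamples, cfg@mkconv@pool1, cfg@mkconv@pool2),
      rfs = as.integer(receptiveField(cfg@tcn@kernel, cfg@tcn@nBlocks)),
      variant = cfg@variant)
}

setClass("ModelSummary", representation(
  perStage = "numeric", detail = "list", total = "numeric",
  tokenCount = "numeric", rfs = "integer", variant = "character"))

#' @rdname countParameters
#' @param k a raw parameter count.
#' @return `roundK` rounds half-up to one decimal in units of 1000.
#' @export
roundK <- function(k) floor(k / 100 + 0.5) / 10

setMethod("show", "ModelSummary", function(object) {
  cat(sprintf("Model variant %s parameter audit\n", object@variant))
  for (st in names(object@perStage)) {
    cat(sprintf("  %-11s %7d  (%.1fk)\n", st, object@perStage[[st]],
                roundK(object@perStage[[st]])))
    d <- object@detail[[st]]
    for (nm in names(d)) cat(sprintf("    %-22s %7d\n", nm, d[[nm]]))
  }
  cat(sprintf("  total       %7d  (%.1fk)\n", object@total, roundK(object@total)))
  cat(sprintf("  T_c = %d tokens, RFS = %d steps\n", object@tokenCount, object@rfs))
  invisible(NULL)
})

#' @rdname countParameters
#' @param object a `ModelSummary`.
#' @export
summaryAsList <- function(object) {
  list(variant = object@variant,
       per_stage = as.list(object@perStage),
       detail = lapply(object@detail, as.list),
       total = object@total, total_k = roundK(object@total),
       token_count = object@tokenCount, rfs = object@rfs)
}

# ---- prediction --------------------------------------------------------------

#' Predict class labels and probabilities
#'
#' Runs a deterministic eval-mode forward pass (dropout and stochastic depth
#' off, batch norm using running statistics) and returns the arg-max labels
#' with ties broken toward the lowest class index, plus softmax probabilities.
#' Requesting a train-mode prediction is an error: stochastic predictions are
#' never meaningful.
#'
#' @param model a trained [TCFormerModel-class].
#' @param batch `[B, C, T]` array or [TrialSet-class].
#' @param mode must remain `"eval"`.
#' @param chunk trials per forward chunk (memory control).
#' @return list with `labels` (integer, 0-based) and `probs` (`B x n_classes`).
#' @export
tcfPredict <- function(model, batch, mode = "eval", chunk = 32L) {
  if (!identical(mode, "eval"))
    stop("prediction must run in eval mode; train-mode outputs are stochastic")
  if (is(batch, "TrialSet")) batch <- signals(batch)
  B <- dim(batch)[1]
  logits <- matrix(0, B, model@config@nClasses)
  for (i0 in seq(1L, B, by = chunk)) {
    idx <- i0:min(B, i0 + chunk - 1L)
    x <- batchToMat(batch[idx, , , drop = FALSE])
    logits[idx, ] <- modelFwd(model, x, length(idx), train = FALSE)$logits
  }
  probs <- softmaxRows(logits)
  labels <- max.col(logits, ties.method = "first") - 1L
  list(labels = labels, probs = probs, logits = logits)
}

#' @rdname tcfPredict
#' @export
predictClasses <- function(model, batch) tcfPredict(model, batch)$labels
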