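#' TrialSet: labeled multichannel EEG trials
#'
#' The universal data currency of the package. Signals are stored as a dense
#' numeric array of shape `trial x channel x time` (microvolts for real
#' recordings; arbitrary units for synthetic data), with one integer class
#' label per trial coded in `0:(nClasses - 1)`, the sampling rate in Hz,
#' ordered channel names, and subject/session provenance tags. Every trial
#' carries a unique id used by the training protocols to assert that
#' standardization statistics, augmentation donors and model updates never
#' touch held-out data.
#'
#' @slot signals numeric array `[n_trials, n_channels, n_samples]`.
#' @slot labels integer vector, one label per trial, values in `[0, nClasses)`.
#' @slot samplingRate sampling rate in Hz (positive scalar).
#' @slot channelNames character vector of length `n_channels`.
#' @slot subjectId subject identifier (scalar string).
#' @slot sessionTag session tag, e.g. `"train"` or `"test"`.
#' @slot nClasses number of classes the label coding refers to.
#' @slot trialIds unique per-trial identifiers.
#' @slot metadata free-form list (augmentation provenance lives here).
#'
#' @aliases TrialSet-class
#' @exportClass TrialSet
setClass("TrialSet",
  representation(
    signals = "array",
    labels = "integer",
    samplingRate = "numeric",
    channelNames = "character",
    subjectId = "character",
    sessionTag = "character",
    nClasses = "integer",
    trialIds = "character",
    metadata = "list"
  )
)

setValidity("TrialSet", function(object) {
  d <- dim(object@signals)
  msgs <- character()
  if (length(d) != 3L)
    msgs <- c(msgs, "signals must be a 3-d array [trial x channel x time]")
  else {
    if (length(object@labels) != d[1L])
      msgs <- c(msgs, sprintf("n_trials (%d) != length(labels) (%d)", d[1L], length(object@labels)))
    if (length(object@channelNames) != d[2L])
      msgs <- c(msgs, "channelNames length must equal n_channels")
    if (length(object@trialIds) != d[1L])
      msgs <- c(msgs, "trialIds length must equal n_trials")
    if (anyDuplicated(object@trialIds))
      msgs <- c(msgs, "trialIds must be unique")
    if (d[1L] > 0 && !all(is.finite(object@signals)))
      msgs <- c(msgs, "signals contain NaN/Inf")
  }
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a positive scalar (Hz)")
  if (length(object@labels) > 0) {
    if (anyNA(object@labels) || any(object@labels < 0L) ||
        any(object@labels >= object@nClasses))
      msgs <- c(msgs, "labels must lie in [0, nClasses)")
  }
  if (object@nClasses < 1L) msgs <- c(msgs, "nClasses must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TrialSet
#'
#' @param signals numeric array `[n_trials, n_channels, n_samples]`.
#' @param labels integer labels in `[0, nClasses)`, one per trial.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames channel names; defaults to `ch1, ch2, ...`.
#' @param subjectId,sessionTag provenance tags.
#' @param nClasses number of classes; defaults to `max(labels) + 1`.
#' @param trialIds unique trial ids; autogenerated from subject/session when
#'   missing.
#' @param metadata free-form list.
#' @return a validated [TrialSet-class] object.
#' @examples
#' ts <- TrialSet(array(rnorm(2 * 3 * 10), c(2, 3, 10)), labels = c(0L, 1L),
#'                samplingRate = 250)
#' nTrials(ts)
#' @export
TrialSet <- function(signals, labels, samplingRate,
                     channelNames = NULL, subjectId = "S1",
                     sessionTag = "train", nClasses = NULL,
                     trialIds = NULL, metadata = list()) {
  signals <- as.array(signals)
  storage.mode(signals) <- "double"
  labels <- as.integer(labels)
  if (is.null(nClasses))
    nClasses <- if (length(labels)) max(labels) + 1L else 1L
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(signals)[2L]))
  if (is.null(trialIds))
    trialIds <- if (dim(signals)[1L] > 0)
      sprintf("%s:%s:%04d", subjectId, sessionTag, seq_len(dim(signals)[1L]))
    else character()
  new("TrialSet",
    signals = signals, labels = labels, samplingRate = as.numeric(samplingRate),
    channelNames = as.character(channelNames), subjectId = as.character(subjectId),
    sessionTag = as.character(sessionTag), nClasses = as.integer(nClasses),
    trialIds = as.character(trialIds), metadata = metadata)
}

#' @rdname TrialSet
#' @param x,object a `TrialSet`.
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))
#' @rdname TrialSet
#' @export
setMethod("signals", "TrialSet", function(x) x@signals)

#' @rdname TrialSet
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname TrialSet
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @rdname TrialSet
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname TrialSet
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@samplingRate)

#' @rdname TrialSet
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname TrialSet
#' @export
setMethod("channelNames", "TrialSet", function(x) x@channelNames)

#' @rdname TrialSet
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname TrialSet
#' @export
setMethod("subjectId", "TrialSet", function(x) x@subjectId)

#' @rdname TrialSet
#' @export
setGeneric("sessionTag", function(x) standardGeneric("sessionTag"))
#' @rdname TrialSet
#' @export
setMethod("sessionTag", "TrialSet", function(x) x@sessionTag)

#' @rdname TrialSet
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @rdname TrialSet
#' @export
setMethod("trialIds", "TrialSet", function(x) x@trialIds)

#' @rdname TrialSet
#' @export
nTrials <- function(x) dim(x@signals)[1L]
#' @rdname TrialSet
#' @export
nChannels <- function(x) dim(x@signals)[2L]
#' @rdname TrialSet
#' @export
nSamples <- function(x) dim(x@signals)[3L]
#' @rdname TrialSet
#' @export
nClasses <- function(x) x@nClasses

#' @describeIn TrialSet subset trials with `ts[i]`.
#' @param i trial indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  i <- seq_len(nTrials(x))[i]
  new("TrialSet",
    signals = x@signals[i, , , drop = FALSE], labels = x@labels[i],
    samplingRate = x@samplingRate, channelNames = x@channelNames,
    subjectId = x@subjectId, sessionTag = x@sessionTag,
    nClasses = x@nClasses, trialIds = x@trialIds[i], metadata = x@metadata)
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@signals)
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@samplingRate))
  cat(sprintf("  subject %s, session %s, %d classes\n",
              object@subjectId, object@sessionTag, object@nClasses))
  if (d[1L] > 0) {
    tab <- table(factor(object@labels, levels = 0:(object@nClasses - 1L)))
    cat("  class counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  if (isTRUE(object@metadata$augmented_any))
    cat("  contains synthetic (augmented) trials\n")
  invisible(NULL)
})

#' Channel-wise mean and standard deviation pooled over trials and time
#'
#' Statistics are pooled over all trials and all time points of each channel
#' (population 1/N convention). Channels whose standard deviation falls below
#' `1e-8` are flagged degenerate; [standardizeTrials()] maps them to zero
#' instead of dividing by a vanishing scale.
#'
#' @param train a non-empty [TrialSet-class]; statistics must always come from
#'   a training split only.
#' @return a `ChannelStats` object with slots `mean`, `sd` and `degenerate`.
#' @export
computeChannelStats <- function(train) {
  stopifnot(is(train, "TrialSet"))
  if (nTrials(train) == 0L) stop("cannot compute channel statistics on an empty TrialSet")
  x <- train@signals                       # [trial, channel, time]
  C <- nChannels(train)
  m <- numeric(C); s <- numeric(C)
  for (c in seq_len(C)) {
    v <- x[, c, ]
    m[c] <- mean(v)
    s[c] <- sqrt(mean((v - m[c])^2))       # population sd
  }
  new("ChannelStats", mean = m, sd = s, degenerate = s < 1e-8,
      channelNames = channelNames(train))
}

#' @rdname computeChannelStats
#' @aliases ChannelStats-class
#' @slot mean,sd per-channel statistics.
#' @slot degenerate logical flags for near-constant channels (sd < 1e-8).
#' @slot channelNames channel names the statistics belong to.
#' @exportClass ChannelStats
setClass("ChannelStats", representation(
  mean = "numeric", sd = "numeric", degenerate = "logical",
  channelNames = "character"))

setValidity("ChannelStats", function(object) {
  if (length(object@mean) != length(object@sd)) return("mean/sd length mismatch")
  if (any(object@sd < 0)) return("sd must be >= 0")
  TRUE
})

setMethod("show", "ChannelStats", function(object) {
  cat(sprintf("ChannelStats over %d channels (%d degenerate)\n",
              length(object@mean), sum(object@degenerate)))
  invisible(NULL)
})

#' Standardize trials with precomputed channel statistics
#'
#' Applies `(x - mean) / max(sd, 1e-8)` per channel. Degenerate channels
#' (flat in the training data) standardize to zero. Statistics must be
#' computed from the training split and then applied unchanged to validation
#' and test data.
#'
#' @param data a [TrialSet-class].
#' @param stats a `ChannelStats` from [computeChannelStats()].
#' @return a standardized `TrialSet`; labels and metadata are untouched.
#' @export
standardizeTrials <- function(data, stats) {
  stopifnot(is(data, "TrialSet"), is(stats, "ChannelStats"))
  C <- nChannels(data)
  if (length(stats@mean) != C)
    stop(sprintf("channel-count mismatch: data has %d channels, stats has %d",
                 C, length(stats@mean)))
  x <- data@signals
  denom <- pmax(stats@sd, 1e-8)
  for (c in seq_len(C)) {
    if (stats@degenerate[c]) x[, c, ] <- 0
    else x[, c, ] <- (x[, c, ] - stats@mean[c]) / denom[c]
  }
  out <- data
  out@signals <- x
  out
}

#' Extract a time window from every trial
#'
#' Windows are half-open sample intervals `[start, start + duration)` with
#' 0-based sample indexing, so a 4 s window at 250 Hz contains exactly 1000
#' samples.
#'
#' @param raw a [TrialSet-class].
#' @param startS window onset in seconds from trial start.
#' @param durationS window length in seconds.
#' @return a `TrialSet` with `round(durationS * fs)` samples per trial.
#' @export
extractWindow <- function(raw, startS, durationS) {
  stopifnot(is(raw, "TrialSet"), startS >= 0, durationS > 0)
  fs <- samplingRate(raw)
  i0 <- round(startS * fs)                 # 0-based first sample
  n <- round(durationS * fs)
  if (i0 + n > nSamples(raw))
    stop(sprintf("window [%g, %g) s needs samples up to %d but trials have only %d",
                 startS, startS + durationS, i0 + n, nSamples(raw)))
  out <- raw
  out@signals <- raw@signals[, , (i0 + 1):(i0 + n), drop = FALSE]
  out
}
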