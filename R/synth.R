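#' Synthetic motor-imagery EEG configuration
#'
#' Describes a class-conditioned oscillatory EEG generator: pink (1/f^alpha)
#' background noise on every channel plus, for each class, amplitude-modulated
#' sinusoidal bursts (mu ~10 Hz / beta ~20 Hz carriers by default) on a
#' class-specific channel subset. The defaults emulate the contralateral
#' sensorimotor topography of a 4-class, 22-channel, 4 s @ 250 Hz recording:
#' disjoint lateralized channel subsets, carrier alternating between the mu
#' and beta bands, modulation depth 0.8, burst amplitude `snr * depth` times
#' the unit noise SD, and 16 trials per class.
#'
#' @param nTrialsPerClass trials per class (default 16).
#' @param nClasses number of classes (default 4).
#' @param nChannels number of EEG channels (default 22).
#' @param nSamples samples per trial (default 1000 = 4 s at 250 Hz).
#' @param fs sampling rate in Hz (default 250).
#' @param classSignatures list with one element per class, each a list of
#'   `channels` (integer subset), `freq` (carrier Hz, must be < fs/2) and
#'   `depth` (modulation depth in `[0, 1]`). `NULL` builds the lateralized
#'   default.
#' @param noiseExponent alpha of the 1/f^alpha background (default 1).
#' @param snr carrier amplitude at depth 1, in units of the noise SD
#'   (default 3, a clean well-responsive-subject regime).
#' @param seed integer; fixes all randomness of [generateSynthEEG()].
#' @return a `SynthConfig` object.
#' @aliases SynthConfig-class
#' @exportClass SynthConfig
#' @export
synthConfig <- function(nTrialsPerClass = 16L, nClasses = 4L, nChannels = 22L,
                        nSamples = 1000L, fs = 250, classSignatures = NULL,
                        noiseExponent = 1, snr = 3, seed = 1L) {
  if (is.null(classSignatures))
    classSignatures <- defaultClassSignatures(nClasses, nChannels, depth = 0.8)
  new("SynthConfig",
      nTrialsPerClass = as.integer(nTrialsPerClass), nClasses = as.integer(nClasses),
      nChannels = as.integer(nChannels), nSamples = as.integer(nSamples),
      fs = as.numeric(fs), classSignatures = classSignatures,
      noiseExponent = as.numeric(noiseExponent), snr = as.numeric(snr),
      seed = as.integer(seed))
}

setClass("SynthConfig", representation(
  nTrialsPerClass = "integer", nClasses = "integer", nChannels = "integer",
  nSamples = "integer", fs = "numeric", classSignatures = "list",
  noiseExponent = "numeric", snr = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (length(object@classSignatures) != object@nClasses)
    msgs <- c(msgs, "one signature per class required")
  for (sig in object@classSignatures) {
    if (sig$depth < 0 || sig$depth > 1) msgs <- c(msgs, "modulation depth must be in [0, 1]")
    if (sig$freq >= object@fs / 2)
      msgs <- c(msgs, sprintf("carrier %g Hz is at or above Nyquist (%g Hz)",
                              sig$freq, object@fs / 2))
    if (any(sig$channels < 1L) || any(sig$channels > object@nChannels))
      msgs <- c(msgs, "signature channels out of range")
  }
  if (length(msgs)) msgs else TRUE
})

# Disjoint lateralized channel subsets with mu/beta carriers, mirroring the
# contralateral organisation of sensorimotor rhythms so that spatial
# (depthwise) filters have realistic structure to learn. Subsets span the
# full montage (nChannels / nClasses channels each), emulating the broad
# spatial extent of sensorimotor rhythm modulations.
defaultClassSignatures <- function(nClasses, nChannels, depth = 0.8) {
  per <- max(1L, nChannels %/% nClasses)
  lapply(seq_len(nClasses), function(k) {
    ch <- ((k - 1L) * per + 1L):(k * per)
    list(channels = as.integer(ch),
         freq = if (k %% 2 == 1) 10 else 20,   # alternate mu / beta carriers
         depth = depth)
  })
}

#' Set a common modulation depth on every class signature
#'
#' @param config a [synthConfig()] object.
#' @param depth new modulation depth in `[0, 1]`.
#' @return the modified config.
#' @export
withModulationDepth <- function(config, depth) {
  config@classSignatures <- lapply(config@classSignatures, function(s) {
    s$depth <- depth; s
  })
  validObject(config)
  config
}

# pink noise via spectral shaping: white gaussian spectra scaled by
# f^(-alpha/2), rescaled to unit variance; one column per channel (the draw
# order matches per-channel sequential generation)
pinkNoiseMatrix <- function(n, k, alpha) {
  white <- matrix(stats::rnorm(n * k), n, k)
  sp <- stats::mvfft(white)
  f <- 0:(n - 1)
  mag <- pmin(f, n - f)                     # two-sided frequency magnitudes
  mag[1] <- 1                               # DC placeholder, zeroed below
  shape <- mag^(-alpha / 2)
  shape[1] <- 0
  x <- Re(stats::mvfft(sp * shape, inverse = TRUE)) / n
  s <- sqrt(colMeans(x^2) - colMeans(x)^2) * sqrt(n / (n - 1))
  s[s <= 0] <- 1
  sweep(x, 2, s, "/")
}

# raised-cosine (Hann) burst envelope covering frac of the trial from a
# random onset; mimics event-related timing variability
burstEnvelope <- function(n, frac, onsetFrac) {
  len <- max(2L, round(frac * n))
  start <- 1L + round(onsetFrac * (n - len))
  env <- numeric(n)
  idx <- start:(start + len - 1L)
  env[idx] <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))
  env
}

#' Generate a synthetic motor-imagery TrialSet
#'
#' Trials are pink-noise background plus, for the trial's class, an
#' amplitude-modulated sinusoidal burst on the class's channel subset. The
#' burst covers a random 50-100% of the trial under a raised-cosine envelope
#' with random onset and phase. Classes are balanced and the result is fully
#' deterministic given `config@seed` (combined with `session`/`subjectId` so
#' different splits draw independent noise).
#'
#' @param config a [synthConfig()].
#' @param subjectId,sessionTag provenance tags for the generated set.
#' @return a [TrialSet-class] with `nTrialsPerClass * nClasses` trials.
#' @export
generateSynthEEG <- function(config, subjectId = "synth1", sessionTag = "train") {
  validObject(config)
  n <- config@nTrialsPerClass * config@nClasses
  C <- config@nChannels; Tn <- config@nSamples
  # independent but reproducible stream per (seed, subject, session)
  tag <- sum(utf8ToInt(paste(subjectId, sessionTag, sep = "/")) *
               seq_along(utf8ToInt(paste(subjectId, sessionTag, sep = "/"))))
  seed <- (as.numeric(config@seed) * 7919 + tag * 104729) %% 2147483647
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  labels <- rep(0:(config@nClasses - 1L), each = config@nTrialsPerClass)
  labels <- labels[sample.int(n)]          # shuffled but balanced
  x <- array(0, c(n, C, Tn))
  tgrid <- (seq_len(Tn) - 1) / config@fs
  for (i in seq_len(n)) {
    x[i, , ] <- t(pinkNoiseMatrix(Tn, C, config@noiseExponent))
    sig <- config@classSignatures[[labels[i] + 1L]]
    if (sig$depth > 0) {
      env <- burstEnvelope(Tn, frac = stats::runif(1, 0.6, 1), onsetFrac = stats::runif(1))
      carrier <- sin(2 * pi * sig$freq * tgrid + stats::runif(1, 0, 2 * pi))
      amp <- config@snr * sig$depth
      for (c in sig$channels) x[i, c, ] <- x[i, c, ] + amp * env * carrier
    } else {
      # draw the same number of variates so depth only scales amplitude
      stats::runif(3)
    }
  }
  TrialSet(x, labels, config@fs, subjectId = subjectId, sessionTag = sessionTag,
           nClasses = config@nClasses)
}

#' Nearest-centroid band-power oracle classifier
#'
#' An intentionally simple, architecture-independent separability check:
#' per-channel log band power (mean periodogram power inside each frequency
#' band), class centroids on the training split, nearest-centroid prediction
#' on the test split. Used to verify that generated data carry the intended
#' class structure before any neural network is involved.
#'
#' @param train,test [TrialSet-class] objects with identical geometry.
#' @param bands list of `c(lo, hi)` frequency intervals in Hz; default the mu
#'   and beta bands.
#' @return overall test accuracy (plain fraction correct; test sets produced
#'   by [generateSynthEEG()] are class-balanced).
#' @export
bandpowerOracle <- function(train, test, bands = list(c(8, 12), c(18, 22))) {
  stopifnot(is(train, "TrialSet"), is(test, "TrialSet"))
  if (length(bands) == 0L) stop("band list must be non-empty")
  if (nChannels(train) != nChannels(test) || nSamples(train) != nSamples(test))
    stop("train/test geometry mismatch")
  featurize <- function(ts) {
    n <- nTrials(ts); C <- nChannels(ts); Tn <- nSamples(ts)
    freqs <- (0:(Tn - 1)) * samplingRate(ts) / Tn
    sel <- lapply(bands, function(b) which(freqs >= b[1] & freqs <= b[2]))
    if (any(vapply(sel, length, integer(1)) == 0L))
      stop("a band contains no periodogram bins")
    feats <- matrix(0, n, C * length(bands))
    for (i in seq_len(n)) {
      for (c in seq_len(C)) {
        p <- Mod(stats::fft(ts@signals[i, c, ]))^2 / Tn
        for (b in seq_along(bands))
          feats[i, (b - 1) * C + c] <- log(mean(p[sel[[b]]]) + 1e-12)
      }
    }
    feats
  }
  ftr <- featurize(train); fte <- featurize(test)
  classes <- 0:(nClasses(train) - 1L)
  centroids <- t(vapply(classes, function(k)
    colMeans(ftr[trialLabels(train) == k, , drop = FALSE]),
    numeric(ncol(ftr))))
  d2 <- outer(rowSums(fte^2), rep(1, length(classes))) -
    2 * fte %*% t(centroids) +
    outer(rep(1, nrow(fte)), rowSums(centroids^2))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == trialLabels(test))
}

#' Build a multi-subject synthetic study
#'
#' Generates train and test sessions for several subjects with shared class
#' signatures (so cross-subject transfer is learnable) but independent noise.
#'
#' @param config a [synthConfig()].
#' @param nSubjects number of subjects.
#' @param nTestPerClass test trials per class (defaults to the training
#'   count).
#' @return a list of [TrialSet-class] objects, two per subject.
#' @export
makeSynthStudy <- function(config, nSubjects = 2L, nTestPerClass = NULL) {
  out <- list()
  for (s in seq_len(nSubjects)) {
    sid <- sprintf("S%02d", s)
    out[[length(out) + 1L]] <- generateSynthEEG(config, sid, "train")
    teCfg <- config
    if (!is.null(nTestPerClass)) teCfg@nTrialsPerClass <- as.integer(nTestPerClass)
    out[[length(out) + 1L]] <- generateSynthEEG(teCfg, sid, "test")
  }
  out
}
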