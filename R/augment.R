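#' Segmentation-and-reconstruction augmentation plan
#'
#' Each trial is cut into `nSegments` equal non-overlapping temporal
#' fragments; synthetic trials are assembled by drawing, independently for
#' every fragment slot, a uniformly random donor trial of the same class and
#' taking its fragment at that slot, so the original temporal order
#' (A-B-...-H) is always preserved. With `nAugmented = nTrials` the training
#' set is doubled.
#'
#' @param nSegments number of temporal fragments N_s (default 8).
#' @param nAugmented total number of synthetic trials to create; allocated to
#'   classes proportionally to their counts (balanced in, balanced out).
#' @param seed RNG seed making the recombination deterministic.
#' @return an `AugmentationPlan`.
#' @aliases AugmentationPlan-class
#' @exportClass AugmentationPlan
#' @export
augmentationPlan <- function(nSegments = 8L, nAugmented, seed = 1L) {
  new("AugmentationPlan", nSegments = as.integer(nSegments),
      nAugmented = as.integer(nAugmented), seed = as.integer(seed))
}

setClass("AugmentationPlan", representation(
  nSegments = "integer", nAugmented = "integer", seed = "integer"))

setValidity("AugmentationPlan", function(object) {
  if (object@nSegments < 1L) return("nSegments must be >= 1")
  if (object@nAugmented < 0L) return("nAugmented must be >= 0")
  TRUE
})

#' Segmentation-and-reconstruction augmentation
#'
#' Returns the original trials unchanged (first, in their original order)
#' followed by `plan@nAugmented` label-preserving synthetic trials. Donors are
#' sampled with replacement, independently per fragment slot, among trials of
#' the same class. Donor indices are recorded in
#' `metadata$donors` (a `nAugmented x nSegments` integer matrix of original
#' trial indices) so every synthetic fragment can be traced byte-for-byte to
#' its source.
#'
#' @param data training-split [TrialSet-class]; `nSamples` must be divisible
#'   by `plan@nSegments` and every class allocated synthetic trials must have
#'   at least one donor.
#' @param plan an [augmentationPlan()].
#' @return a `TrialSet` with `nTrials(data) + plan@nAugmented` trials.
#' @export
segmentAndReconstruct <- function(data, plan) {
  stopifnot(is(data, "TrialSet"), is(plan, "AugmentationPlan"))
  m <- nTrials(data); Ns <- plan@nSegments; Tn <- nSamples(data)
  if (Tn %% Ns != 0L)
    stop(sprintf("n_samples (%d) must be divisible by nSegments (%d)", Tn, Ns))
  fragLen <- Tn %/% Ns
  labs <- trialLabels(data)
  counts <- table(factor(labs, levels = 0:(nClasses(data) - 1L)))

  # proportional per-class allocation of the synthetic total (largest
  # remainders absorb the rounding)
  alloc <- integer(length(counts))
  if (plan@nAugmented > 0L) {
    if (m == 0L) stop("cannot augment an empty TrialSet")
    raw <- as.numeric(counts) / m * plan@nAugmented
    alloc <- floor(raw)
    rem <- plan@nAugmented - sum(alloc)
    if (rem > 0) {
      order_rem <- order(raw - alloc, decreasing = TRUE)
      alloc[order_rem[seq_len(rem)]] <- alloc[order_rem[seq_len(rem)]] + 1L
    }
    if (any(alloc > 0L & as.integer(counts) == 0L))
      stop("a class with zero trials was allocated synthetic trials")
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(plan@seed)

  mA <- sum(alloc)
  out <- array(0, c(m + mA, nChannels(data), Tn))
  out[seq_len(m), , ] <- data@signals
  newLabs <- integer(mA)
  donors <- matrix(0L, mA, Ns)
  row <- 0L
  for (k in seq_along(alloc)) {
    cls <- k - 1L
    pool <- which(labs == cls)
    for (r in seq_len(alloc[k])) {
      row <- row + 1L
      newLabs[row] <- cls
      d <- pool[sample.int(length(pool), Ns, replace = TRUE)]
      donors[row, ] <- d
      for (s in seq_len(Ns)) {
        idx <- ((s - 1L) * fragLen + 1L):(s * fragLen)
        out[m + row, , idx] <- data@signals[d[s], , idx]
      }
    }
  }
  md <- data@metadata
  md$augmented <- c(rep(FALSE, m), rep(TRUE, mA))
  md$donors <- donors
  md$donor_ids <- trialIds(data)
  md$augmented_any <- mA > 0L
  TrialSet(out, c(labs, newLabs), samplingRate(data),
           channelNames = channelNames(data), subjectId = subjectId(data),
           sessionTag = sessionTag(data), nClasses = nClasses(data),
           trialIds = c(trialIds(data),
                        if (mA) sprintf("%s:aug:%04d", subjectId(data), seq_len(mA))),
           metadata = md)
}
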