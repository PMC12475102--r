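#' Neutral binary trial store
#'
#' A single-file hierarchical container that round-trips [TrialSet-class]
#' objects bit-exactly and decouples the pipeline from benchmark file formats.
#' Layout: an 8-byte magic (`"TCFSTOR1"`), a little-endian 64-bit header
#' length, a JSON header describing every entry (dims, labels, sampling rate,
#' channel names, subject, session, trial ids, metadata, byte offset of the
#' signal block), then the concatenated signal blocks as little-endian IEEE-754
#' float64 in R's native `[trial, channel, time]` column-major order.
#'
#' A store may hold one `TrialSet` or a collection (e.g. all subjects and
#' sessions of a study).
#'
#' @param x a `TrialSet` or a list of `TrialSet`s.
#' @param path file path.
#' @return `writeTrialStore` returns `path` invisibly; `readTrialStore`
#'   returns a `TrialSet` when the selection is unique, otherwise a list of
#'   `TrialSet`s.
#' @export
writeTrialStore <- function(x, path) {
  if (is(x, "TrialSet")) x <- list(x)
  stopifnot(all(vapply(x, function(e) is(e, "TrialSet"), logical(1))))
  entries <- list(); offset <- 0
  for (e in x) {
    d <- dim(e@signals)
    entries[[length(entries) + 1L]] <- list(
      dims = as.integer(d),
      labels = e@labels,
      fs = e@samplingRate,
      channel_names = e@channelNames,
      subject = e@subjectId,
      session = e@sessionTag,
      n_classes = e@nClasses,
      trial_ids = e@trialIds,
      metadata = e@metadata,
      offset = offset,
      n_values = prod(d)
    )
    offset <- offset + prod(d) * 8
  }
  hdr <- jsonlite::toJSON(list(format = "tcformer-trial-store", version = 1L,
                               entries = entries),
                          auto_unbox = TRUE, digits = NA, null = "null")
  hdr_raw <- charToRaw(as.character(hdr))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("TCFSTOR1"), con)
  writeBin(as.numeric(length(hdr_raw)), con, size = 8, endian = "little")
  writeBin(hdr_raw, con)
  for (e in x)
    if (length(e@signals)) writeBin(as.numeric(e@signals), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeTrialStore
#' @param subject,session optional selectors; `NULL` keeps everything.
#' @export
readTrialStore <- function(path, subject = NULL, session = NULL) {
  if (!file.exists(path)) stop("trial store not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, "TCFSTOR1")) stop("not a tcformer trial store: ", path)
  hlen <- readBin(con, "numeric", 1, size = 8, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                            simplifyVector = FALSE)
  data_start <- 16 + hlen
  out <- list()
  for (ent in hdr$entries) {
    for (f in c("dims", "fs", "subject", "session"))
      if (is.null(ent[[f]])) stop(sprintf("trial store entry: %s missing", f))
    if (is.null(ent$labels) && ent$dims[[1]] > 0) stop("labels missing")
    d <- vapply(ent$dims, as.integer, integer(1))
    if (!is.null(subject) && !identical(as.character(ent$subject), as.character(subject))) next
    if (!is.null(session) && !identical(as.character(ent$session), as.character(session))) next
    seek(con, data_start + ent$offset)
    vals <- readBin(con, "numeric", ent$n_values, size = 8, endian = "little")
    md <- if (is.null(ent$metadata)) list() else storeMetadataThaw(ent$metadata)
    out[[length(out) + 1L]] <- TrialSet(
      signals = array(vals, d),
      labels = as.integer(unlist(ent$labels, use.names = FALSE)),
      samplingRate = ent$fs,
      channelNames = as.character(unlist(ent$channel_names, use.names = FALSE)),
      subjectId = ent$subject, sessionTag = ent$session,
      nClasses = as.integer(ent$n_classes),
      trialIds = as.character(unlist(ent$trial_ids, use.names = FALSE)),
      metadata = md)
  }
  if (length(out) == 0L) stop("no matching entries in trial store")
  if (length(out) == 1L) out[[1L]] else out
}

# JSON round-trips lists of scalars as lists; restore the shapes the
# augmentation metadata uses (integer matrix of donors, flags, id vectors).
storeMetadataThaw <- function(md) {
  if (!is.null(md$donors)) {
    dn <- md$donors
    md$donors <- matrix(as.integer(unlist(dn)), nrow = length(dn), byrow = TRUE)
  }
  if (!is.null(md$augmented))
    md$augmented <- as.logical(unlist(md$augmented, use.names = FALSE))
  if (!is.null(md$donor_ids))
    md$donor_ids <- as.character(unlist(md$donor_ids, use.names = FALSE))
  if (!is.null(md$augmented_any)) md$augmented_any <- isTRUE(md$augmented_any[[1]] == TRUE) ||
    isTRUE(md$augmented_any)
  md
}

#' Read a BCI Competition IV GDF recording (optional benchmark adapter)
#'
#' Thin adapter that epochs a GDF file into a [TrialSet-class]: EEG channels
#' only (EOG dropped), cue-locked windows, labels remapped to
#' `0:(n_classes-1)`. GDF parsing is delegated to the Python `mne` package via
#' the system `python`; the adapter therefore requires a Python interpreter
#' with `mne` on the `PATH`. Benchmark files themselves are never downloaded
#' by this package.
#'
#' @param path GDF file.
#' @param spec a [datasetSpec()] describing geometry and windowing.
#' @param labels optional integer vector of true labels (the competition
#'   distributes evaluation-session labels separately).
#' @param python python executable.
#' @return a `TrialSet`.
#' @export
readGDF <- function(path, spec, labels = NULL, python = "python") {
  if (!file.exists(path)) stop("GDF file not found: ", path)
  helper <- system.file("python", "read_gdf.py", package = "tcformer")
  if (!nzchar(helper)) stop("bundled GDF helper script not found")
  out_store <- tempfile(fileext = ".tcfstore")
  args <- c(helper, path, out_store,
            as.character(spec@windowStart), as.character(spec@windowSeconds),
            as.character(spec@fs), spec@name)
  status <- suppressWarnings(system2(python, shQuote(args), stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("GDF adapter failed (is python+mne available?):\n",
         paste(status, collapse = "\n"))
  ts <- readTrialStore(out_store)
  unlink(out_store)
  if (!is.null(labels)) {
    ts@labels <- as.integer(labels)
    validObject(ts)
  }
  if (nChannels(ts) != spec@nChannels)
    warning(sprintf("expected %d EEG channels, got %d", spec@nChannels, nChannels(ts)))
  ts
}

#' Dataset geometry specification
#'
#' Describes a benchmark's geometry and epoching: channel count, class count,
#' cue-locked window, sampling rate and train/test session mapping.
#'
#' @param name dataset name (`"bcic4-2a"`, `"bcic4-2b"`, `"hgd"`, ...).
#' @param nChannels,nClasses,fs geometry.
#' @param windowStart window onset in seconds relative to recording events.
#' @param windowSeconds window duration in seconds; `windowSeconds * fs` must
#'   be a positive integer.
#' @param trainSessions,testSessions session labels for the protocol split.
#' @return a `DatasetSpec` object.
#' @aliases DatasetSpec-class
#' @exportClass DatasetSpec
#' @export
datasetSpec <- function(name, nChannels, nClasses, windowStart, windowSeconds, fs,
                        trainSessions = "train", testSessions = "test") {
  new("DatasetSpec", name = name, nChannels = as.integer(nChannels),
      nClasses = as.integer(nClasses), windowStart = windowStart,
      windowSeconds = windowSeconds, fs = fs,
      trainSessions = trainSessions, testSessions = testSessions)
}

setClass("DatasetSpec", representation(
  name = "character", nChannels = "integer", nClasses = "integer",
  windowStart = "numeric", windowSeconds = "numeric", fs = "numeric",
  trainSessions = "character", testSessions = "character"))

setValidity("DatasetSpec", function(object) {
  n <- object@windowSeconds * object@fs
  if (n <= 0 || abs(n - round(n)) > 1e-9)
    return("windowSeconds * fs must be a positive integer")
  TRUE
})

#' Built-in dataset specifications
#'
#' `bcic4-2a`: 22 EEG channels, 4 classes, 250 Hz, the 4 s motor-imagery
#' window (2-6 s after trial onset). `bcic4-2b`: 3 channels, 2 classes,
#' 250 Hz, the 3-7 s window (the 4.5 s-imagery sessions are cropped to the
#' same 4 s so every trial has T = 1000 samples). `hgd`: 44 motor-cortex
#' channels (configurable), 4 classes, 250 Hz after downsampling.
#'
#' @param name one of `"bcic4-2a"`, `"bcic4-2b"`, `"hgd"`.
#' @return a `DatasetSpec`.
#' @export
builtinDatasetSpec <- function(name = c("bcic4-2a", "bcic4-2b", "hgd")) {
  switch(match.arg(name),
    "bcic4-2a" = datasetSpec("bcic4-2a", 22, 4, windowStart = 2, windowSeconds = 4, fs = 250),
    "bcic4-2b" = datasetSpec("bcic4-2b", 3, 2, windowStart = 3, windowSeconds = 4, fs = 250),
    "hgd"      = datasetSpec("hgd", 44, 4, windowStart = 0, windowSeconds = 4, fs = 250))
}
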