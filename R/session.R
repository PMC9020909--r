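#' Construct an EEG session
#'
#' @param data numeric matrix, channels x samples (microvolts). Rows are
#'   named from `montage` if unnamed.
#' @param samplingRate sampling frequency in Hz (study default 250).
#' @param montage a [Montage-class]; defaults to [standardMontage()].
#' @param events data.frame with columns `onset` (0-based sample index)
#'   and `label` ("fear"/"neutral").
#' @return an [EEGSession-class].
#' @export
EEGSession <- function(data, samplingRate = 250, montage = standardMontage(),
                       events = data.frame(onset = integer(),
                                           label = character())) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  rownames(data) <- montage@channels
  events <- as.data.frame(events)
  events$onset <- as.integer(events$onset)
  events$label <- factor(as.character(events$label),
                         levels = c("fear", "neutral"))
  new("EEGSession", data = data, samplingRate = as.numeric(samplingRate),
      montage = montage, events = events)
}

#' @rdname EEGSession
#' @param x an object with a sampling rate.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGSession
#' @export
setMethod("samplingRate", "EEGSession", function(x) x@samplingRate)

#' @rdname EEGSession
#' @export
setMethod("samplingRate", "TrialEpoch", function(x) x@samplingRate)

#' @rdname EEGSession
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname EEGSession
#' @export
setMethod("eventTable", "EEGSession", function(x) x@events)

#' @rdname EEGSession
#' @export
setGeneric("sessionData", function(x) standardGeneric("sessionData"))

#' @rdname EEGSession
#' @export
setMethod("sessionData", "EEGSession", function(x) x@data)

setMethod("show", "EEGSession", function(object) {
  ev <- table(object@events$label)
  cat(sprintf(paste0("EEGSession: %d channels x %d samples @ %g Hz ",
                     "(%.1f s)\n  events: %d (fear %d / neutral %d)\n"),
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate,
              nrow(object@events), ev[["fear"]], ev[["neutral"]]))
})

setMethod("show", "TrialEpoch", function(object) {
  cat(sprintf(paste0("TrialEpoch [%s]: %d ch, baseline %d + stimulus %d ",
                     "samples @ %g Hz\n  processing: %s\n"),
              object@label, length(object@channels), ncol(object@baseline),
              ncol(object@stimulus), object@samplingRate,
              if (length(object@processing))
                paste(object@processing, collapse = " -> ") else "(raw)"))
})

## ---------------------------------------------------------------------
## Fixture container: line 1 is a JSON header {fs, channels, reference,
## ground, events:{onset[],label[]}}; each following line is one channel
## row, whitespace-separated "%.17g" doubles (bit-exact round trip).
## ---------------------------------------------------------------------

#' Read / write EEG sessions
#'
#' `readSession()` loads a session from the package's plain-text fixture
#' container (`format = "fixture"`, see README for the layout) or from a
#' 16-bit EDF file (`format = "edf"`). `writeSession()` writes the
#' fixture container; fixture round trips are bit-exact.
#'
#' EDF channels are matched against the montage by label; non-EEG
#' channels (triggers, EOG, ...) are dropped by name with a warning,
#' and unknown EEG labels are an error. EDF event annotations are read
#' from an accompanying `<file>.events` table written by [writeEDF()]
#' (plain TSV: onset, label).
#'
#' @param path file path.
#' @param format "fixture" or "edf".
#' @param montage montage to validate channel labels against.
#' @param samplingRate expected sampling rate; an EDF at a different
#'   rate raises a `ResampleNotSupportedError` (resampling is out of
#'   scope).
#' @return an [EEGSession-class].
#' @export
readSession <- function(path, format = c("fixture", "edf"),
                        montage = standardMontage(), samplingRate = 250) {
  format <- match.arg(format)
  if (!file.exists(path)) ffStop("FileError", paste("no such file:", path))
  if (format == "fixture") readFixture(path, montage)
  else readSessionEDF(path, montage, samplingRate)
}

#' @rdname readSession
#' @param session an [EEGSession-class] to write.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "EEGSession"))
  header <- jsonlite::toJSON(list(
    format = "fearfuse-fixture-v1",
    fs = session@samplingRate,
    channels = session@montage@channels,
    reference = session@montage@reference,
    ground = session@montage@ground,
    events = list(onset = session@events$onset,
                  label = as.character(session@events$label))),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")  # "wb": fixed \n endings on every platform
  on.exit(close(con))
  writeLines(as.character(header), con)
  d <- session@data
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatExact(d[i, ]), collapse = " "), con)
  invisible(path)
}

readFixture <- function(path, montage) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[[1]])
  if (!identical(header$format, "fearfuse-fixture-v1"))
    ffStop("FileError", "not a fearfuse fixture file")
  chans <- header$channels
  if (!identical(chans, montage@channels)) {
    unknown <- setdiff(chans, montage@channels)
    if (length(unknown))
      ffStop("ChannelError",
             paste("unknown channels:", paste(unknown, collapse = ", ")))
    ffStop("ChannelError", "fixture channel order differs from montage")
  }
  rows <- lapply(lines[-1], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  d <- do.call(rbind, rows)
  if (is.null(header$events$onset) || length(header$events$onset) == 0)
    ffStop("EventError", "fixture has no events")
  EEGSession(d, samplingRate = header$fs, montage = montage,
             events = data.frame(onset = header$events$onset,
                                 label = header$events$label))
}

## ---------------------------------------------------------------------
## Epoching
## ---------------------------------------------------------------------

#' Cut a session into labeled trial epochs
#'
#' One epoch per event: the `baselineSec` seconds preceding the onset
#' and the `stimulusSec` seconds from the onset (half-open windows,
#' 0-based sample indices). Labels are copied from the event table.
#'
#' @param session an [EEGSession-class].
#' @param baselineSec pre-stimulus baseline length in seconds (default 1).
#' @param stimulusSec stimulus length in seconds (study default 30).
#' @return list of [TrialEpoch-class], one per event.
#' @export
epochSession <- function(session, baselineSec = 1, stimulusSec = 30) {
  stopifnot(is(session, "EEGSession"))
  fs <- session@samplingRate
  nPre <- round(baselineSec * fs)
  nStim <- round(stimulusSec * fs)
  ev <- session@events
  if (nrow(ev) == 0) ffStop("EventError", "session has no events")
  nSamp <- ncol(session@data)
  lapply(seq_len(nrow(ev)), function(i) {
    onset <- ev$onset[i]
    if (onset - nPre < 0 || onset + nStim > nSamp)
      ffStop("EpochBoundsError", sprintf(
        "event %d at sample %d: needs %d samples before and %d after",
        i, onset, nPre, nStim))
    ## 0-based onsets: sample index k is column k+1
    new("TrialEpoch", label = as.character(ev$label[i]),
        baseline = session@data[, (onset - nPre + 1):onset, drop = FALSE],
        stimulus = session@data[, (onset + 1):(onset + nStim), drop = FALSE],
        samplingRate = fs, channels = session@montage@channels,
        processing = character())
  })
}

#' @rdname epochSession
#' @param x a [TrialEpoch-class].
#' @export
setGeneric("trialLabel", function(x) standardGeneric("trialLabel"))

#' @rdname epochSession
#' @export
setMethod("trialLabel", "TrialEpoch", function(x) x@label)
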