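## Minimal EDF (European Data Format) support: 16-bit integer encoding,
## one-second data records, all signals at the session sampling rate.
## Event markers travel in a plain-TSV sidecar "<file>.events" (onset,
## label) rather than EDF+ annotation channels; writeEDF() emits it and
## readSession(format = "edf") requires it.

.padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

## labels like "EEG Fp1-A2" resolve to "Fp1"; plain "Fp1" stays put
.resolveEDFLabel <- function(label) {
  l <- trimws(label)
  l <- sub("^EEG[ .]", "", l)
  sub("-.*$", "", l)
}

.NON_EEG_PREFIX <- c("EOG", "ECG", "EMG", "EKG", "Status", "Trigger",
                     "Marker", "Annotations", "Resp", "Temp")

#' Write a session as a 16-bit EDF file
#'
#' Signals are scaled to the full 16-bit digital range per channel, so
#' re-reading reproduces the data to within one quantization step of
#' `(max - min) / 65535` per channel. The recording length must be a
#' whole number of seconds (one-second data records). Events are written
#' to a `<path>.events` TSV sidecar.
#'
#' @param session an [EEGSession-class].
#' @param path output path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @seealso [readSession()]
#' @export
writeEDF <- function(session, path) {
  stopifnot(is(session, "EEGSession"))
  fs <- session@samplingRate
  if (abs(fs - round(fs)) > 0)
    ffStop("FileError", "EDF writer needs an integer sampling rate")
  d <- session@data
  ns <- nrow(d)
  if (ncol(d) %% fs != 0)
    ffStop("FileError",
           "EDF writer needs a whole number of 1-second records")
  nrec <- ncol(d) %/% fs
  pmin <- apply(d, 1, min); pmax <- apply(d, 1, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(.padField(x, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(nrec, 8); wr(1, 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(paste("EEG", rownames(d)[i]), 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", pmin[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", pmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  ## physical min/max are re-parsed from their 8-char ascii fields so the
  ## digital->physical map used here matches what a reader will apply
  pminA <- as.numeric(sprintf("%.2f", pmin))
  pmaxA <- as.numeric(sprintf("%.2f", pmax))
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((d[i, cols] - pminA[i]) / (pmaxA[i] - pminA[i]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  ev <- session@events
  utils::write.table(
    data.frame(onset = ev$onset, label = as.character(ev$label)),
    paste0(path, ".events"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

readSessionEDF <- function(path, montage, samplingRate) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                    # transducer
  for (i in seq_len(ns)) rd(8)                     # dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                    # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  fsSig <- spr / recDur
  resolved <- vapply(labels, .resolveEDFLabel, "")
  isNonEEG <- vapply(resolved, function(l)
    any(startsWith(toupper(l), toupper(.NON_EEG_PREFIX))), TRUE)
  keep <- which(!isNonEEG)
  if (any(isNonEEG))
    ffWarn("ChannelWarning", paste("dropping non-EEG channels:",
           paste(resolved[isNonEEG], collapse = ", ")))
  unknown <- setdiff(resolved[keep], montage@channels)
  if (length(unknown))
    ffStop("ChannelError", paste("unknown EEG channels:",
           paste(unknown, collapse = ", ")))
  if (!setequal(resolved[keep], montage@channels))
    ffStop("ChannelError", "EDF does not contain the full montage")
  if (any(fsSig[keep] != samplingRate))
    ffStop("ResampleNotSupportedError", sprintf(
      "EDF sampling rate %g != expected %g (resampling not supported)",
      fsSig[keep][1], samplingRate))
  nSamp <- nrec * spr
  d <- matrix(0, length(resolved), max(nSamp))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (i %in% keep)
        d[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
          (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) +
          pmin[i]
    }
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- resolved[keep]
  d <- d[montage@channels, , drop = FALSE]
  evPath <- paste0(path, ".events")
  if (!file.exists(evPath))
    ffStop("EventError", paste("no event sidecar:", evPath))
  ev <- utils::read.table(evPath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(ev) == 0) ffStop("EventError", "event sidecar is empty")
  EEGSession(d, samplingRate = samplingRate, montage = montage,
             events = ev)
}
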