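#' Power spectral density estimate
#'
#' One-sided, density-scaled periodogram of a 1-second window, computed
#' by zero-padded discrete Fourier transform (default length 1024).
#'
#' @slot freqs frequency grid in Hz (0 .. Nyquist).
#' @slot power channels x bins matrix, uV^2/Hz, non-negative.
#' @slot nfft transform length used.
#' @export
setClass("PSDEstimate",
  representation(freqs = "numeric", power = "matrix", nfft = "integer"),
  validity = function(object) {
    if (any(object@power < 0)) return("power must be non-negative")
    if (is.unsorted(object@freqs)) return("freqs must be monotone")
    if (ncol(object@power) != length(object@freqs))
      return("one power column per frequency")
    TRUE
  })

#' Periodogram of a segment via zero-padded DFT
#'
#' Each channel's window is zero-padded to `nfft` points (default 1024,
#' a power of two for a 250-sample window) and transformed; the
#' one-sided periodogram is density-scaled so that the integral of the
#' PSD over frequency equals the window's mean square value.
#'
#' @param x a [Segment-class] or numeric matrix (channels x samples).
#' @param nfft transform length, >= window length; a non-power-of-two
#'   value is allowed with a warning.
#' @param fs sampling rate (taken from the segment when given one).
#' @param taper "none" (default) or "hann".
#' @return a [PSDEstimate-class].
#' @export
computePSD <- function(x, nfft = 1024, fs = NULL,
                       taper = c("none", "hann")) {
  taper <- match.arg(taper)
  if (is(x, "Segment")) { fs <- x@samplingRate; x <- x@data }
  stopifnot(is.matrix(x), isScalarNumber(fs))
  n <- ncol(x)
  if (n > nfft) ffStop("PSDError", "window longer than nfft")
  if (bitwAnd(nfft, nfft - 1L) != 0L)
    ffWarn("PSDWarning", "nfft is not a power of two")
  w <- rep(1, n)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    w <- w / sqrt(mean(w^2))          # preserve density scaling
  }
  padded <- rbind(t(x * rep(w, each = nrow(x))),
                  matrix(0, nfft - n, nrow(x)))
  X <- stats::mvfft(padded)
  half <- nfft %/% 2 + 1L
  p <- Mod(X[seq_len(half), , drop = FALSE])^2 / (fs * n)
  p[2:(half - 1L), ] <- 2 * p[2:(half - 1L), ]   # fold negative freqs
  new("PSDEstimate", freqs = (seq_len(half) - 1) * fs / nfft,
      power = t(p), nfft = as.integer(nfft))
}

#' Mean band power from a PSD
#'
#' Per channel, the mean of PSD values over bins with
#' `band@low <= f <= band@high` (closed on both ends on the DFT grid).
#'
#' @param psd a [PSDEstimate-class].
#' @param band a [FrequencyBand-class].
#' @return named numeric vector, one value per channel.
#' @export
bandPower <- function(psd, band) {
  stopifnot(is(psd, "PSDEstimate"), is(band, "FrequencyBand"))
  sel <- psd@freqs >= band@low & psd@freqs <= band@high
  if (!any(sel))
    ffStop("BandError", sprintf("band %s has no bins on this grid",
                                band@name))
  rowMeans(psd@power[, sel, drop = FALSE])
}

#' Differential entropy of a Gaussian band-limited signal
#'
#' The Gaussian closed form `DE = 1/2 * ln(2*pi*e*sigma^2)` (nats),
#' with `sigma^2` the band-power estimate. DE is a logarithmic
#' band-power feature: scaling the signal by `a` adds `ln|a|` exactly.
#' Non-positive power is floored at 1e-20 with a warning.
#'
#' @param power numeric vector of band-power values.
#' @return numeric vector of DE values in nats.
#' @export
differentialEntropy <- function(power) {
  if (any(!is.finite(power))) ffStop("DEError", "non-finite band power")
  if (any(power <= 0)) {
    ffWarn("DEWarning", "non-positive band power floored at 1e-20")
    power <- pmax(power, .POWER_FLOOR)
  }
  0.5 * log(2 * pi * exp(1) * power)
}

#' Differential-entropy feature block of a trial
#'
#' For every 1-second segment, the channels x bands DE matrix flattened
#' band-major (all channels of delta, then theta, ...); 150 columns for
#' the default 30-channel montage and 5-band bank.
#'
#' @param epoch a preprocessed [TrialEpoch-class] (pipeline tags
#'   baseline/notch/bandpass required).
#' @param bands list of [FrequencyBand-class] (default [defaultBands()]).
#' @param nfft transform length for the zero-padded periodogram.
#' @param windowSec,stepSec segmentation grid (default 1 s, 1 s).
#' @param source "spectral" (default): sigma^2 from the mean band power
#'   of the zero-padded periodogram; "variance": sigma^2 from the
#'   time-domain variance of the band-filtered segment.
#' @param taper periodogram taper, see [computePSD()].
#' @return numeric matrix, segments x (channels * bands), with feature
#'   names "DE|band|channel".
#' @export
deFeatures <- function(epoch, bands = defaultBands(), nfft = 1024,
                       windowSec = 1, stepSec = 1,
                       source = c("spectral", "variance"),
                       taper = "none") {
  source <- match.arg(source)
  .requireSteps(epoch, c("baseline", "notch", "bandpass"))
  segs <- segmentTrial(epoch, windowSec, stepSec)
  chans <- epoch@channels
  out <- matrix(NA_real_, length(segs), length(chans) * length(bands))
  if (source == "spectral") {
    for (s in seq_along(segs)) {
      psd <- computePSD(segs[[s]]@data, nfft, epoch@samplingRate, taper)
      out[s, ] <- unlist(lapply(bands, function(b)
        differentialEntropy(bandPower(psd, b))), use.names = FALSE)
    }
  } else {
    fs <- epoch@samplingRate
    for (bi in seq_along(bands)) {
      filt <- bandFilter(epoch@stimulus, bands[[bi]], fs = fs)
      for (s in seq_along(segs)) {
        idx <- (segs[[s]]@windowIndex - 1L) * round(stepSec * fs)
        cols <- (idx + 1):(idx + round(windowSec * fs))
        v <- apply(filt[, cols, drop = FALSE], 1, stats::var)
        out[s, (bi - 1) * length(chans) + seq_along(chans)] <-
          differentialEntropy(v)
      }
    }
  }
  colnames(out) <- unlist(lapply(bands, function(b)
    paste("DE", b@name, chans, sep = "|")), use.names = FALSE)
  out
}

.requireSteps <- function(epoch, steps) {
  base <- sub(":.*$", "", epoch@processing)
  missing <- setdiff(steps, base)
  if (length(missing))
    ffStop("PipelineOrderError", paste(
      "epoch missing preprocessing step(s):",
      paste(missing, collapse = ", ")))
  invisible(TRUE)
}
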