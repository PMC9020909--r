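#' Preprocessing filter specification
#'
#' Defaults follow the study pipeline: 50 Hz power-line notch (biquad,
#' Q = 30, about 1.7 Hz -3 dB width) and a tenth-order 0.1-70 Hz
#' Butterworth bandpass, both applied zero-phase (forward-backward).
#'
#' @slot notchFreq notch center frequency in Hz.
#' @slot notchQ notch quality factor (center / -3 dB width).
#' @slot bandpassLow,bandpassHigh broadband edges in Hz.
#' @slot bandpassOrder effective bandpass order (even, >= 2).
#' @export
setClass("FilterSpec",
  representation(notchFreq = "numeric", notchQ = "numeric",
                 bandpassLow = "numeric", bandpassHigh = "numeric",
                 bandpassOrder = "numeric"),
  validity = function(object) {
    if (object@bandpassLow <= 0 ||
        object@bandpassHigh <= object@bandpassLow)
      return("need 0 < bandpassLow < bandpassHigh")
    if (object@bandpassOrder < 2 || object@bandpassOrder %% 2 != 0)
      return("bandpassOrder must be even and >= 2")
    TRUE
  })

#' @rdname FilterSpec-class
#' @param notchFreq,notchQ,bandpassLow,bandpassHigh,bandpassOrder see slots.
#' @return a `FilterSpec`.
#' @export
filterSpec <- function(notchFreq = 50, notchQ = 30, bandpassLow = 0.1,
                       bandpassHigh = 70, bandpassOrder = 10) {
  new("FilterSpec", notchFreq = notchFreq, notchQ = notchQ,
      bandpassLow = bandpassLow, bandpassHigh = bandpassHigh,
      bandpassOrder = bandpassOrder)
}

## ---------------------------------------------------------------------
## pipeline-state tags: steps must be applied in this order, each once
## ---------------------------------------------------------------------
.STEP_RANK <- c(baseline = 1, notch = 2, bandpass = 3, band = 4)

.advanceState <- function(processing, step) {
  base <- sub(":.*$", "", step)
  rank <- .STEP_RANK[[base]]
  applied <- .STEP_RANK[sub(":.*$", "", processing)]
  if (length(applied) && rank <= max(applied))
    ffStop("PipelineOrderError", sprintf(
      "step '%s' cannot follow '%s' (fixed order: %s)", step,
      processing[length(processing)],
      paste(names(.STEP_RANK), collapse = " -> ")))
  c(processing, step)
}

## ---------------------------------------------------------------------
## filter kernels
## ---------------------------------------------------------------------

## RBJ biquad notch at f0 with quality Q
.notchCoefs <- function(f0, Q, fs) {
  if (f0 >= fs / 2) ffStop("FilterDesignError", "notch above Nyquist")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

.butterBand <- function(low, high, order, fs) {
  ny <- fs / 2
  if (!(low > 0 && high > low && high < ny))
    ffStop("FilterDesignError",
           sprintf("band [%g, %g] Hz invalid at fs = %g", low, high, fs))
  flt <- signal::butter(order / 2, c(low, high) / ny, type = "pass")
  if (any(!is.finite(flt$b)) || any(!is.finite(flt$a)) ||
      any(Mod(polyroot(rev(flt$a))) >= 1 + 1e-8))
    ffStop("FilterDesignError", paste(
      "unstable Butterworth design at this sampling rate;",
      "consider a second-order-sections implementation"))
  flt
}

## steady-state unit-step initial state of a direct-form-II-transposed
## filter (the lfilter_zi construction): starting from zi * x[1]
## removes the startup transient of slow (near-DC) poles
.filterZi <- function(b, a) {
  n <- max(length(a), length(b))
  if (n < 2) return(numeric(0))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  comp <- rbind(-a[2:n], cbind(diag(1, n - 2, n - 2),
                               numeric(n - 2)))
  B <- b[2:n] - b[1] * a[2:n]
  as.vector(solve(diag(n - 1) - t(comp), B))
}

## direct-form IIR filter of matrix columns, steady-state-initialized
.iirFilterCols <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  .iirFilterColsC(b, a, X, .filterZi(b, a))
}

## factor a transfer function into second-order sections (conjugate
## pole pairs, nearest zeros), the numerically robust realization for
## higher-order designs with poles near the unit circle
.sosSections <- function(b, a) {
  k <- b[1] / a[1]
  zeros <- if (length(b) > 1) polyroot(rev(b / b[1])) else complex(0)
  poles <- if (length(a) > 1) polyroot(rev(a / a[1])) else complex(0)
  ## order poles by closeness to the unit circle (most critical first)
  poles <- poles[order(-Mod(poles))]
  secs <- list()
  usedZ <- rep(FALSE, length(zeros))
  while (length(poles) > 0) {
    p1 <- poles[1]; poles <- poles[-1]
    if (abs(Im(p1)) > 1e-10) {
      j <- which.min(Mod(poles - Conj(p1)))
      p2 <- poles[j]; poles <- poles[-j]
    } else if (length(poles) > 0) {
      reals <- which(abs(Im(poles)) <= 1e-10)
      j <- reals[which.min(Mod(poles[reals] - p1))]
      p2 <- poles[j]; poles <- poles[-j]
    } else p2 <- NULL
    zz <- c()
    for (r in 1:2) {
      free <- which(!usedZ)
      if (length(free) == 0) break
      j <- free[which.min(Mod(zeros[free] - p1))]
      usedZ[j] <- TRUE
      zz <- c(zz, zeros[j])
    }
    bs <- Re(c(1, -sum(zz), if (length(zz) == 2) prod(zz) else 0))
    if (length(zz) == 0) bs <- c(1, 0, 0)
    if (length(zz) == 1) bs <- c(1, -Re(zz), 0)
    as <- if (!is.null(p2)) Re(c(1, -(p1 + p2), p1 * p2))
          else c(1, -Re(p1), 0)
    secs[[length(secs) + 1]] <- list(b = bs, a = as)
  }
  secs[[1]]$b <- secs[[1]]$b * k
  secs
}

.sosApply <- function(secs, X) {
  for (s in secs) X <- .iirFilterCols(s$b, s$a, X)
  X
}

## zero-phase (forward-backward) or causal application, rows =
## channels, run as a cascade of steady-state-initialized biquads;
## forward-backward passes use odd-reflection padding
.filterMatrix <- function(mat, flt, zeroPhase = TRUE) {
  secs <- .sosSections(flt$b, flt$a)
  X <- t(mat)
  if (!zeroPhase) return(t(.sosApply(secs, X)))
  n <- nrow(X)
  pad <- min(n - 1L, max(9L * length(secs), 50L))
  first <- X[1, ]; last <- X[n, ]
  front <- 2 * rep(1, pad) %o% first - X[(pad + 1):2, , drop = FALSE]
  back <- 2 * rep(1, pad) %o% last - X[(n - 1):(n - pad), , drop = FALSE]
  Y <- .sosApply(secs, rbind(front, X, back))
  Y <- Y[nrow(Y):1, , drop = FALSE]
  Y <- .sosApply(secs, Y)
  Y <- Y[nrow(Y):1, , drop = FALSE]
  t(Y[(pad + 1):(pad + n), , drop = FALSE])
}

.applyEpochFilter <- function(epoch, flt, tag, zeroPhase) {
  new("TrialEpoch", label = epoch@label,
      baseline = .filterMatrix(epoch@baseline, flt, zeroPhase),
      stimulus = .filterMatrix(epoch@stimulus, flt, zeroPhase),
      samplingRate = epoch@samplingRate, channels = epoch@channels,
      processing = .advanceState(epoch@processing, tag))
}

## ---------------------------------------------------------------------
## operations
## ---------------------------------------------------------------------

#' Baseline-correct a trial epoch
#'
#' Subtracts, per channel, the mean of the 1-second pre-stimulus
#' baseline from the stimulus window. The baseline itself is retained
#' unchanged for audit.
#'
#' @param epoch a [TrialEpoch-class].
#' @return the corrected [TrialEpoch-class] (processing tag "baseline").
#' @export
baselineCorrect <- function(epoch) {
  stopifnot(is(epoch, "TrialEpoch"))
  if (ncol(epoch@baseline) == 0)
    ffStop("PreprocessError", "zero-length baseline")
  mu <- rowMeans(epoch@baseline)
  new("TrialEpoch", label = epoch@label, baseline = epoch@baseline,
      stimulus = epoch@stimulus - mu, samplingRate = epoch@samplingRate,
      channels = epoch@channels,
      processing = .advanceState(epoch@processing, "baseline"))
}

#' Power-line notch filter
#'
#' Zero-phase second-order IIR (biquad) notch at `spec@notchFreq`
#' (default 50 Hz, Q = 30). Output length equals input length.
#'
#' @param x a [TrialEpoch-class] or [EEGSession-class].
#' @param spec a [FilterSpec-class].
#' @param zeroPhase apply forward-backward (default) or causal.
#' @return same type as `x`.
#' @export
notchFilter <- function(x, spec = filterSpec(), zeroPhase = TRUE) {
  fs <- samplingRate(x)
  flt <- .notchCoefs(spec@notchFreq, spec@notchQ, fs)
  if (is(x, "TrialEpoch"))
    return(.applyEpochFilter(x, flt, "notch", zeroPhase))
  stopifnot(is(x, "EEGSession"))
  initialize(x, data = .filterMatrix(x@data, flt, zeroPhase))
}

#' Broadband bandpass filter
#'
#' Zero-phase Butterworth bandpass of effective order
#' `spec@bandpassOrder` (default 10) between `spec@bandpassLow` and
#' `spec@bandpassHigh` Hz (default 0.1-70).
#'
#' @inheritParams notchFilter
#' @return same type as `x`.
#' @export
bandpassFilter <- function(x, spec = filterSpec(), zeroPhase = TRUE) {
  fs <- samplingRate(x)
  flt <- .butterBand(spec@bandpassLow, spec@bandpassHigh,
                     spec@bandpassOrder, fs)
  if (is(x, "TrialEpoch"))
    return(.applyEpochFilter(x, flt, "bandpass", zeroPhase))
  stopifnot(is(x, "EEGSession"))
  initialize(x, data = .filterMatrix(x@data, flt, zeroPhase))
}

#' Restrict a trial to one frequency band
#'
#' Zero-phase 4th-order Butterworth restricted to `[band@low,
#' band@high]`; the per-band step feeding the CSP and PLV paths.
#'
#' @param x a [TrialEpoch-class] (or numeric matrix, rows = channels).
#' @param band a [FrequencyBand-class].
#' @param order effective filter order (default 4).
#' @param zeroPhase forward-backward (default) or causal.
#' @param fs sampling rate, only needed for plain matrices.
#' @return same type as `x`.
#' @export
bandFilter <- function(x, band, order = 4, zeroPhase = TRUE, fs = NULL) {
  if (is(x, "TrialEpoch")) {
    flt <- .butterBand(band@low, band@high, order, samplingRate(x))
    return(.applyEpochFilter(x, flt, paste0("band:", band@name),
                             zeroPhase))
  }
  stopifnot(is.matrix(x), isScalarNumber(fs))
  .filterMatrix(x, .butterBand(band@low, band@high, order, fs), zeroPhase)
}

#' Convenience: the fixed preprocessing chain
#'
#' baseline correction -> 50 Hz notch -> broadband bandpass, the order
#' asserted by the pipeline-state tags.
#'
#' @inheritParams baselineCorrect
#' @inheritParams notchFilter
#' @return preprocessed [TrialEpoch-class].
#' @export
preprocessEpoch <- function(epoch, spec = filterSpec(), zeroPhase = TRUE) {
  bandpassFilter(notchFilter(baselineCorrect(epoch), spec, zeroPhase),
                 spec, zeroPhase)
}

#' Segment a trial's stimulus into sliding windows
#'
#' Half-open windows `[start, start + window)` over the stimulus, by
#' default non-overlapping 1-second windows: 30 segments for a 30-s
#' trial. Each segment inherits the trial label.
#'
#' @param epoch a [TrialEpoch-class].
#' @param windowSec window length in seconds.
#' @param stepSec step between window starts in seconds.
#' @param trialIndex index recorded on each segment (provenance).
#' @return list of [Segment-class].
#' @export
segmentTrial <- function(epoch, windowSec = 1, stepSec = 1,
                         trialIndex = 1L) {
  stopifnot(is(epoch, "TrialEpoch"))
  if (stepSec <= 0) ffStop("SegmentError", "step must be positive")
  fs <- epoch@samplingRate
  nWin <- round(windowSec * fs)
  nStep <- round(stepSec * fs)
  nStim <- ncol(epoch@stimulus)
  if (nWin > nStim)
    ffStop("SegmentError", "window longer than the stimulus")
  starts <- seq(0L, nStim - nWin, by = nStep)
  lapply(seq_along(starts), function(k) {
    new("Segment", trialIndex = as.integer(trialIndex),
        windowIndex = as.integer(k),
        data = epoch@stimulus[, (starts[k] + 1):(starts[k] + nWin),
                              drop = FALSE],
        label = epoch@label, samplingRate = fs)
  })
}
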