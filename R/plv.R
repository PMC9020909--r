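#' Instantaneous phase series of band-filtered channels
#'
#' Phase of the analytic signal (Hilbert-transform construction),
#' computed per channel over the whole trial so that windowing can skip
#' the transform's edge artifacts. Values lie in (-pi, pi].
#'
#' @slot values channels x samples phase matrix, radians.
#' @slot band the [FrequencyBand-class] of the input.
#' @slot samplingRate Hz.
#' @export
setClass("PhaseSeries",
  representation(values = "matrix", band = "FrequencyBand",
                 samplingRate = "numeric"))

#' @rdname PhaseSeries-class
#' @param x a band-filtered [TrialEpoch-class] (tag "band:<name>"
#'   required) or a numeric channels x samples matrix.
#' @param band the band the input was filtered in.
#' @param fs sampling rate (matrices only).
#' @return a [PhaseSeries-class].
#' @export
instantaneousPhase <- function(x, band, fs = NULL) {
  if (is(x, "TrialEpoch")) {
    .requireSteps(x, "band")
    fs <- x@samplingRate
    x <- x@stimulus
  }
  stopifnot(is.matrix(x), isScalarNumber(fs))
  zero <- which(apply(x, 1, function(r) all(r == 0)))
  if (length(zero))
    ffStop("ZeroSignalError", paste(
      "phase undefined for all-zero channel(s):",
      paste(if (!is.null(rownames(x))) rownames(x)[zero] else zero,
            collapse = ", ")))
  new("PhaseSeries", values = .analyticPhase(x), band = band,
      samplingRate = fs)
}

## FFT analytic-signal phase, rows = channels
.analyticPhase <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  X <- stats::mvfft(t(x)) * h
  t(Arg(stats::mvfft(X, inverse = TRUE)))   # scale cancels in Arg
}

#' Phase-locking value between two phase series
#'
#' For each sliding window, `PLV = |mean over window samples of
#' exp(i * (phix - phiy))|`: 1 for perfectly locked phases, tending to
#' the Rayleigh floor ~1/sqrt(N) for independent phases. The default
#' step is 0.4 s between window starts.
#'
#' @param phaseX,phaseY numeric phase vectors (radians), equal length.
#' @param fs sampling rate in Hz.
#' @param windowSec window length in seconds (default 1).
#' @param stepSec step between window starts in seconds (default 0.4).
#' @return numeric vector, one PLV per window position.
#' @export
plvPair <- function(phaseX, phaseY, fs, windowSec = 1, stepSec = 0.4) {
  stopifnot(length(phaseX) == length(phaseY))
  nWin <- round(windowSec * fs)
  nStep <- round(stepSec * fs)
  if (nWin < 1 || nWin > length(phaseX))
    ffStop("WindowError", "empty or over-long PLV window")
  starts <- seq(0L, length(phaseX) - nWin, by = nStep)
  u <- exp(1i * (phaseX - phaseY))
  vapply(starts, function(s0) Mod(mean(u[(s0 + 1):(s0 + nWin)])),
         numeric(1))
}

## row-major upper-triangle pair index (i < j), the fixed ENP order
.pairIndex <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i, j)
}

## all-pairs PLV matrices for every 0.4-s-stepped window of a phase
## matrix, plus the 1-s segment each window's center falls in
.windowPLV <- function(phase, fs, windowSec = 1, stepSec = 0.4,
                       edgeSec = 0.1, segSec = 1) {
  n <- ncol(phase)
  nWin <- round(windowSec * fs)
  nEdge <- round(edgeSec * fs)
  starts <- seq(nEdge, n - nEdge - nWin, by = round(stepSec * fs))
  U <- exp(1i * phase)
  nSeg <- floor(n / (segSec * fs))
  segOf <- pmin(floor((starts + nWin / 2) / (segSec * fs)) + 1L, nSeg)
  mats <- lapply(starts, function(s0) {
    Z <- U[, (s0 + 1):(s0 + nWin), drop = FALSE]
    Mod(Z %*% Conj(t(Z))) / nWin
  })
  list(mats = mats, segment = segOf, nSeg = nSeg)
}

#' Per-segment PLV connectivity matrices of a trial
#'
#' Band-filters the preprocessed trial, extracts instantaneous phases
#' over the whole trial, computes all-pairs PLV in 1-second windows
#' stepped by 0.4 s (the first and last 0.1 s excluded from window
#' placement), and aggregates to the 1-second analysis segments shared
#' with the DE/CSP paths by averaging the windows whose centers fall in
#' each segment.
#'
#' @param epoch a preprocessed [TrialEpoch-class].
#' @param band a [FrequencyBand-class].
#' @param windowSec,stepSec PLV window length and step (1 s, 0.4 s).
#' @param edgeSec trial edge excluded from window placement.
#' @return list of [PLVMatrix-class], one per 1-s segment.
#' @export
plvMatrices <- function(epoch, band, windowSec = 1, stepSec = 0.4,
                        edgeSec = 0.1) {
  .requireSteps(epoch, c("baseline", "notch", "bandpass"))
  fs <- epoch@samplingRate
  filt <- bandFilter(epoch@stimulus, band, fs = fs)
  ph <- instantaneousPhase(filt, band, fs = fs)
  w <- .windowPLV(ph@values, fs, windowSec, stepSec, edgeSec)
  lapply(seq_len(w$nSeg), function(s) {
    sel <- which(w$segment == s)
    m <- Reduce(`+`, w$mats[sel]) / length(sel)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    new("PLVMatrix", values = pmin(pmax(m, 0), 1), band = band,
        channels = epoch@channels)
  })
}

#' Network-pattern (pairwise-PLV) feature block of a trial
#'
#' Per segment and band, the strict upper triangle of the PLV matrix
#' flattened in row-major montage order, bands concatenated band-major:
#' 435 pairs x 5 bands = 2175 columns on the default montage.
#'
#' @param epoch a preprocessed [TrialEpoch-class].
#' @param bands list of [FrequencyBand-class].
#' @param windowSec,stepSec,edgeSec see [plvMatrices()].
#' @return numeric matrix, segments x (pairs * bands), feature names
#'   "ENP|band|chI-chJ".
#' @export
enpFeatures <- function(epoch, bands = defaultBands(), windowSec = 1,
                        stepSec = 0.4, edgeSec = 0.1) {
  chans <- epoch@channels
  pairs <- .pairIndex(length(chans))
  blocks <- lapply(bands, function(b) {
    mats <- plvMatrices(epoch, b, windowSec, stepSec, edgeSec)
    t(vapply(mats, function(m) m@values[pairs], numeric(nrow(pairs))))
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(bands, function(b)
    paste("ENP", b@name, paste0(chans[pairs[, 1]], "-",
                                chans[pairs[, 2]]), sep = "|")),
    use.names = FALSE)
  out
}

#' Edge-wise differential-connectivity ANOVA
#'
#' For every channel pair, a one-way analysis of variance across trials
#' on the trial-mean PLV (fear vs. neutral). The set of edges with
#' `p < alpha` is the paired differential network for the band. For two
#' groups the F statistic equals the squared pooled two-sample t
#' statistic. (The source analysis is described both as repeated
#' measures and as one-way ANOVA; one-way across trials is implemented
#' here.)
#'
#' @param epochs list of preprocessed [TrialEpoch-class] with labels.
#' @param band a [FrequencyBand-class].
#' @param alpha significance level for flagging edges.
#' @param correction "none" (default) or "BH" (Benjamini-Hochberg).
#' @param windowSec,stepSec,edgeSec see [plvMatrices()].
#' @return data.frame with columns channel1, channel2, band, F, p,
#'   significant; channel1 precedes channel2 in montage order.
#' @export
connectivityAnova <- function(epochs, band, alpha = 0.05,
                              correction = c("none", "BH"),
                              windowSec = 1, stepSec = 0.4,
                              edgeSec = 0.1) {
  correction <- match.arg(correction)
  labels <- vapply(epochs, trialLabel, "")
  if (length(unique(labels)) < 2)
    ffStop("StatsError", "need trials from both classes")
  chans <- epochs[[1]]@channels
  pairs <- .pairIndex(length(chans))
  ## trial-mean PLV per pair: average over all sliding windows
  vals <- t(vapply(epochs, function(ep) {
    fs <- ep@samplingRate
    filt <- bandFilter(ep@stimulus, band, fs = fs)
    ph <- .analyticPhase(filt)
    w <- .windowPLV(ph, fs, windowSec, stepSec, edgeSec)
    (Reduce(`+`, w$mats) / length(w$mats))[pairs]
  }, numeric(nrow(pairs))))
  .edgeAnova(vals, labels, chans, pairs, band, alpha, correction)
}

## vals: trials x pairs matrix of trial-mean PLV
.edgeAnova <- function(vals, labels, chans, pairs, band, alpha,
                       correction = "none") {
  g <- factor(labels)
  stat <- apply(vals, 2, function(v) {
    if (stats::var(v) == 0) return(c(0, 1))      # identical everywhere
    ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
    f <- unname(ow$statistic); p <- ow$p.value
    if (!is.finite(f)) { f <- Inf; p <- 0 }      # zero within-group var
    c(f, p)
  })
  p <- if (correction == "BH") stats::p.adjust(stat[2, ], "BH")
       else stat[2, ]
  data.frame(channel1 = chans[pairs[, 1]], channel2 = chans[pairs[, 2]],
             band = band@name, F = stat[1, ], p = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}
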