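#' Extract all per-segment features of a session once
#'
#' Runs the fixed preprocessing chain on every trial and computes, per
#' 1-second segment: the DE block, the ENP (pairwise PLV) block, and
#' the per-band raw segment scatter matrices `E %*% t(E)` that the
#' fold-wise CSP fits and CSP features are derived from. Computing the
#' scatter matrices once is what makes leakage-free per-fold CSP
#' refitting affordable inside [loocv()].
#'
#' @param session an [EEGSession-class].
#' @param bands filter bank (default [defaultBands()]).
#' @param spec a [FilterSpec-class] for preprocessing.
#' @param windowSec,stepSec segmentation grid (default 1 s, 1 s).
#' @param plvStepSec PLV window step (default 0.4 s).
#' @param nfft periodogram transform length (default 1024).
#' @param baselineSec,stimulusSec epoching windows (1 s, 30 s).
#' @param deSource see [deFeatures()].
#' @return list with elements `de`, `enp` (segments x features
#'   matrices), `covs` (per band: 3-d array channels x channels x
#'   segments of raw scatter), `traces` (per band: segment scatter
#'   traces), `segmentInfo`, `bands`, `channels`.
#' @export
sessionFeatureCache <- function(session, bands = defaultBands(),
                                spec = filterSpec(), windowSec = 1,
                                stepSec = 1, plvStepSec = 0.4,
                                nfft = 1024, baselineSec = 1,
                                stimulusSec = 30,
                                deSource = "spectral") {
  epochs <- lapply(epochSession(session, baselineSec, stimulusSec),
                   preprocessEpoch, spec = spec)
  fs <- session@samplingRate
  chans <- channelNames(session)
  nChan <- length(chans)
  nWin <- round(windowSec * fs)
  nStep <- round(stepSec * fs)
  nSegPer <- length(seq(0L, ncol(epochs[[1]]@stimulus) - nWin,
                        by = nStep))
  nSeg <- nSegPer * length(epochs)
  pairs <- .pairIndex(nChan)

  de <- matrix(NA_real_, nSeg, nChan * length(bands))
  enp <- matrix(NA_real_, nSeg, nrow(pairs) * length(bands))
  covs <- lapply(bands, function(b)
    array(NA_real_, c(nChan, nChan, nSeg)))
  for (tr in seq_along(epochs)) {
    ep <- epochs[[tr]]
    rows <- ((tr - 1) * nSegPer + 1):(tr * nSegPer)
    de[rows, ] <- deFeatures(ep, bands, nfft, windowSec, stepSec,
                             source = deSource)
    starts <- seq(0L, ncol(ep@stimulus) - nWin, by = nStep)
    for (bi in seq_along(bands)) {
      filt <- bandFilter(ep@stimulus, bands[[bi]], fs = fs)
      for (k in seq_along(starts)) {
        seg <- filt[, (starts[k] + 1):(starts[k] + nWin), drop = FALSE]
        covs[[bi]][, , rows[k]] <- tcrossprod(seg)
      }
      ph <- .analyticPhase(filt)
      w <- .windowPLV(ph, fs, windowSec, plvStepSec, segSec = windowSec)
      ecols <- (bi - 1) * nrow(pairs) + seq_len(nrow(pairs))
      for (s in seq_len(w$nSeg)) {
        sel <- which(w$segment == s)
        m <- Reduce(`+`, w$mats[sel]) / length(sel)
        enp[rows[s], ecols] <- ((m + t(m)) / 2)[pairs]
      }
    }
  }
  colnames(de) <- unlist(lapply(bands, function(b)
    paste("DE", b@name, chans, sep = "|")), use.names = FALSE)
  colnames(enp) <- unlist(lapply(bands, function(b)
    paste("ENP", b@name, paste0(chans[pairs[, 1]], "-",
                                chans[pairs[, 2]]), sep = "|")),
    use.names = FALSE)
  list(de = de, enp = enp, covs = covs,
       traces = lapply(covs, function(a) apply(a, 3, function(m)
         sum(diag(m)))),
       segmentInfo = data.frame(
         trial = rep(seq_along(epochs), each = nSegPer),
         window = rep(seq_len(nSegPer), length(epochs)),
         label = rep(vapply(epochs, trialLabel, ""), each = nSegPer),
         stringsAsFactors = FALSE),
       bands = bands, channels = chans)
}

#' Fuse feature blocks into one segment-indexed feature set
#'
#' Column-concatenates the enabled blocks in the fixed order DE, ENP,
#' CSP. Single-block sets (for the per-feature comparison grid) are
#' obtained by passing only that block.
#'
#' @param de,enp,csp segments x features matrices (any may be `NULL`),
#'   with matching rows.
#' @param segmentInfo data.frame with trial, window, label per row.
#' @param blocks character subset of c("DE", "ENP", "CSP") to enable.
#' @return a [FusedFeatureSet-class].
#' @export
fuseFeatures <- function(de = NULL, enp = NULL, csp = NULL, segmentInfo,
                         blocks = c("DE", "ENP", "CSP")) {
  avail <- list(DE = de, ENP = enp, CSP = csp)
  blocks <- intersect(c("DE", "ENP", "CSP"), blocks)   # fixed order
  use <- avail[blocks]
  use <- use[!vapply(use, is.null, TRUE)]
  if (length(use) == 0)
    ffStop("AlignmentError", "no feature blocks enabled")
  nr <- vapply(use, nrow, 0L)
  if (length(unique(nr)) != 1 || nr[1] != nrow(segmentInfo))
    ffStop("AlignmentError", "feature blocks have misaligned segments")
  values <- do.call(cbind, use)
  widths <- vapply(use, ncol, 0L)
  ends <- cumsum(widths)
  blockIdx <- Map(function(w, e) seq(e - w + 1, e), widths, ends)
  new("FusedFeatureSet", values = values, blocks = blockIdx,
      featureNames = colnames(values),
      segmentInfo = as.data.frame(segmentInfo))
}

#' @rdname fuseFeatures
#' @param x a [FusedFeatureSet-class].
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname fuseFeatures
#' @export
setMethod("featureMatrix", "FusedFeatureSet", function(x) x@values)

#' @rdname fuseFeatures
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname fuseFeatures
#' @export
setMethod("featureBlocks", "FusedFeatureSet", function(x) x@blocks)

#' @rdname fuseFeatures
#' @export
setGeneric("segmentInfo", function(x) standardGeneric("segmentInfo"))

#' @rdname fuseFeatures
#' @export
setMethod("segmentInfo", "FusedFeatureSet", function(x) x@segmentInfo)

setMethod("show", "FusedFeatureSet", function(object) {
  w <- vapply(object@blocks, length, 0L)
  cat(sprintf("FusedFeatureSet: %d segments x %d features (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s:%d", names(w), w), collapse = ", ")))
})

## restrict a cache-derived feature matrix to one band by name prefix
.bandColumns <- function(featureNames, bandName) {
  if (identical(bandName, "all")) return(seq_along(featureNames))
  which(vapply(strsplit(featureNames, "|", fixed = TRUE),
               function(p) p[2] == bandName, TRUE))
}
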