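#' @import methods
NULL

#' Electrode montage
#'
#' An ordered set of 10-20 system electrode labels together with the
#' reference and ground electrode names. Channel order is fixed at
#' construction and preserved through every stage of the pipeline; all
#' downstream objects (sessions, epochs, feature names) inherit it.
#'
#' @slot channels character vector of unique 10-20 labels, in order.
#' @slot reference label of the reference electrode.
#' @slot ground label of the ground electrode.
#'
#' @seealso [standardMontage()] for the default 30-channel layout.
#' @export
setClass("Montage",
  representation(channels = "character", reference = "character",
                 ground = "character"),
  validity = function(object) {
    if (anyDuplicated(object@channels))
      return("channel names must be unique")
    if (length(object@channels) < 2L)
      return("a montage needs at least two channels")
    TRUE
  })

#' Frequency band definition
#'
#' A named frequency interval \[low, high\] in Hz used by the filter
#' bank. The canonical EEG bank is returned by [defaultBands()].
#'
#' @slot name band name, e.g. "alpha".
#' @slot low lower edge in Hz (> 0).
#' @slot high upper edge in Hz (> low).
#' @export
setClass("FrequencyBand",
  representation(name = "character", low = "numeric", high = "numeric"),
  validity = function(object) {
    if (!isScalarNumber(object@low) || !isScalarNumber(object@high))
      return("band edges must be single finite numbers")
    if (object@low <= 0 || object@high <= object@low)
      return("band edges must satisfy 0 < low < high")
    TRUE
  })

#' Multichannel EEG recording with event markers
#'
#' A channels-by-samples matrix of EEG (microvolts) at a fixed sampling
#' rate, plus a montage and an event table marking stimulus onsets with
#' class labels ("fear"/"neutral").
#'
#' @slot data numeric matrix, channels x samples, rows named by channel.
#' @slot samplingRate sampling frequency in Hz.
#' @slot montage a [Montage-class] object; row count of `data` must match.
#' @slot events data.frame with integer column `onset` (0-based sample
#'   index of stimulus onset) and factor column `label` with levels
#'   fear, neutral.
#' @export
setClass("EEGSession",
  representation(data = "matrix", samplingRate = "numeric",
                 montage = "Montage", events = "data.frame"),
  validity = function(object) {
    if (!isScalarNumber(object@samplingRate) || object@samplingRate <= 0)
      return("samplingRate must be a positive number")
    if (nrow(object@data) != length(object@montage@channels))
      return("data row count must equal montage size")
    if (!identical(rownames(object@data), object@montage@channels))
      return("data rownames must equal montage channel order")
    ev <- object@events
    if (!all(c("onset", "label") %in% names(ev)))
      return("events needs columns onset and label")
    if (nrow(ev) > 0) {
      if (!is.numeric(ev$onset) || any(ev$onset != floor(ev$onset)))
        return("event onsets must be integer sample indices")
      if (!all(as.character(ev$label) %in% c("fear", "neutral")))
        return("event labels must be 'fear' or 'neutral'")
      if (any(ev$onset < 0) || any(ev$onset >= ncol(object@data)))
        return("event onsets must lie inside the recording")
    }
    TRUE
  })

#' One labeled trial: 1 s pre-stimulus baseline plus stimulus window
#'
#' @slot label "fear" or "neutral".
#' @slot baseline channels x pre-samples matrix (pre-stimulus).
#' @slot stimulus channels x stim-samples matrix.
#' @slot samplingRate Hz.
#' @slot channels channel names, in montage order.
#' @slot processing character vector of applied preprocessing steps, in
#'   order (pipeline-state tag: "baseline", "notch", "bandpass",
#'   "band:<name>").
#' @export
setClass("TrialEpoch",
  representation(label = "character", baseline = "matrix",
                 stimulus = "matrix", samplingRate = "numeric",
                 channels = "character", processing = "character"),
  validity = function(object) {
    if (!object@label %in% c("fear", "neutral"))
      return("label must be 'fear' or 'neutral'")
    if (nrow(object@baseline) != length(object@channels) ||
        nrow(object@stimulus) != length(object@channels))
      return("baseline/stimulus rows must match channel count")
    if (ncol(object@baseline) < 1L)
      return("baseline must be non-empty")
    TRUE
  })

#' One 1-second analysis window of a trial
#'
#' @slot trialIndex index of the parent trial (1-based).
#' @slot windowIndex index of the window within the trial (1-based).
#' @slot data channels x window-samples matrix.
#' @slot label inherited trial label.
#' @slot samplingRate Hz.
#' @export
setClass("Segment",
  representation(trialIndex = "integer", windowIndex = "integer",
                 data = "matrix", label = "character",
                 samplingRate = "numeric"))

#' Fitted common-spatial-pattern model for one frequency band
#'
#' Rows of `filters` are spatial filters ordered by descending
#' eigenvalue of the whitened class-1 covariance; `selected` indexes the
#' first three and last three rows (the most discriminative ends).
#'
#' @slot band a [FrequencyBand-class].
#' @slot filters channels x channels matrix of spatial filters (rows).
#' @slot selected integer vector of 6 selected row indices.
#' @slot eigenvalues eigenvalues in \[0, 1\], descending.
#' @slot classOrder character(2): class whose variance the first rows
#'   maximize, then the other class.
#' @export
setClass("CSPModel",
  representation(band = "FrequencyBand", filters = "matrix",
                 selected = "integer", eigenvalues = "numeric",
                 classOrder = "character"),
  validity = function(object) {
    n <- nrow(object@filters)
    if (ncol(object@filters) != n) return("filters must be square")
    if (length(object@selected) != 6L) return("exactly 6 selected rows")
    if (length(object@eigenvalues) != n)
      return("one eigenvalue per filter")
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
      return("eigenvalues must be sorted descending")
    if (any(object@eigenvalues < -1e-8 | object@eigenvalues > 1 + 1e-8))
      return("eigenvalues must lie in [0, 1]")
    TRUE
  })

#' Symmetric phase-locking-value connectivity matrix
#'
#' @slot values channels x channels matrix in \[0, 1\], symmetric with
#'   unit diagonal.
#' @slot band the [FrequencyBand-class] the phases were extracted in.
#' @slot channels channel names.
#' @export
setClass("PLVMatrix",
  representation(values = "matrix", band = "FrequencyBand",
                 channels = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("PLV matrix must be square")
    if (max(abs(v - t(v))) > 1e-12) return("PLV matrix must be symmetric")
    if (any(v < -1e-12 | v > 1 + 1e-12)) return("PLV values must be in [0,1]")
    if (max(abs(diag(v) - 1)) > 1e-12) return("PLV diagonal must be 1")
    TRUE
  })

#' Segment-indexed fused feature matrix
#'
#' Rows are 1-second segments (trial x window); columns are named
#' features grouped into blocks DE (activation), ENP (connectivity) and
#' CSP (spatial), concatenated in that fixed order.
#'
#' @slot values numeric matrix, segments x features.
#' @slot blocks named list mapping block name to its column indices.
#' @slot featureNames character vector "block|band|detail" per column.
#' @slot segmentInfo data.frame with columns trial, window, label.
#' @export
setClass("FusedFeatureSet",
  representation(values = "matrix", blocks = "list",
                 featureNames = "character", segmentInfo = "data.frame"),
  validity = function(object) {
    if (ncol(object@values) != length(object@featureNames))
      return("one feature name per column")
    if (nrow(object@values) != nrow(object@segmentInfo))
      return("one segmentInfo row per feature row")
    if (length(object@blocks) == 0) return("at least one block")
    idx <- unlist(object@blocks, use.names = FALSE)
    if (!identical(sort(idx), seq_len(ncol(object@values))))
      return("block indices must partition the columns")
    if (any(!is.finite(object@values)))
      return("feature values must be finite")
    TRUE
  })

#' Trained linear segment classifier
#'
#' Linear hinge-loss SVM (C = 1) fitted on z-scored segment features,
#' with the normalization statistics and primal weight vector retained
#' so per-channel weight maps can be derived.
#'
#' @slot weights primal weight vector over (kept) fused features.
#' @slot bias intercept.
#' @slot center,scale per-feature training mean / sd.
#' @slot keep logical vector: features retained (non-constant in training).
#' @slot featureNames names of all input features.
#' @slot blocks block->column map of the training feature set.
#' @slot levels class labels, c("fear", "neutral").
#' @export
setClass("ClassifierModel",
  representation(weights = "numeric", bias = "numeric", center = "numeric",
                 scale = "numeric", keep = "logical",
                 featureNames = "character", blocks = "list",
                 levels = "character"))

#' Leave-one-out cross-validation result
#'
#' @slot folds data.frame with one row per held-out trial: trial, truth,
#'   predicted, votesFear, votesNeutral, tie.
#' @slot accuracy percent correct over trials.
#' @slot config list snapshot (blocks, bands, options).
#' @export
setClass("CVResult",
  representation(folds = "data.frame", accuracy = "numeric",
                 config = "list"),
  validity = function(object) {
    ok <- mean(object@folds$truth == object@folds$predicted) * 100
    if (abs(ok - object@accuracy) > 1e-9)
      return("accuracy must equal 100 * mean per-fold correctness")
    TRUE
  })
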