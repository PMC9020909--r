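#' The default 30-channel 10-20 montage
#'
#' Twelve symmetric electrode pairs (Fp1-Fp2, F7-F8, F3-F4, FT7-FT8,
#' FC3-FC4, T7-T8, P7-P8, C3-C4, TP7-TP8, CP3-CP4, P3-P4, O1-O2) plus
#' the six midline electrodes Fz, FCz, Cz, CPz, Pz, Oz; right mastoid
#' reference, forehead ground. This order is the canonical channel
#' order of the whole pipeline.
#'
#' @return a [Montage-class] with 30 channels.
#' @examples
#' m <- standardMontage()
#' length(channelNames(m))
#' @export
standardMontage <- function() {
  pairs <- c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "FT7", "FT8",
             "FC3", "FC4", "T7", "T8", "P7", "P8", "C3", "C4",
             "TP7", "TP8", "CP3", "CP4", "P3", "P4", "O1", "O2")
  midline <- c("Fz", "FCz", "Cz", "CPz", "Pz", "Oz")
  new("Montage", channels = c(pairs, midline),
      reference = "A2", ground = "Fpz")
}

#' Construct a frequency band
#'
#' @param name band name.
#' @param low,high edges in Hz, 0 < low < high.
#' @return a [FrequencyBand-class].
#' @export
frequencyBand <- function(name, low, high) {
  new("FrequencyBand", name = as.character(name),
      low = as.numeric(low), high = as.numeric(high))
}

#' The canonical five-band EEG filter bank
#'
#' delta 1-3, theta 4-7, alpha 8-13, beta 14-30, gamma 31-48 Hz.
#' Edges are overridable by constructing bands with [frequencyBand()].
#'
#' @return named list of [FrequencyBand-class] objects in fixed order.
#' @export
defaultBands <- function() {
  list(delta = frequencyBand("delta", 1, 3),
       theta = frequencyBand("theta", 4, 7),
       alpha = frequencyBand("alpha", 8, 13),
       beta  = frequencyBand("beta", 14, 30),
       gamma = frequencyBand("gamma", 31, 48))
}

#' @describeIn standardMontage channel names of a montage or session.
#' @param x object with channels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname standardMontage
#' @export
setMethod("channelNames", "Montage", function(x) x@channels)

#' @rdname standardMontage
#' @export
setMethod("channelNames", "EEGSession", function(x) x@montage@channels)

#' @rdname standardMontage
#' @export
setMethod("channelNames", "TrialEpoch", function(x) x@channels)

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d channels (ref %s, gnd %s)\n",
              length(object@channels), object@reference, object@ground))
  cat(" ", paste(object@channels, collapse = " "), "\n")
})

setMethod("show", "FrequencyBand", function(object) {
  cat(sprintf("FrequencyBand %s: %g-%g Hz\n",
              object@name, object@low, object@high))
})
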