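## Shared fixtures: small sessions kept cheap for unit tests. The
## full-size study conditions (40 trials x 30 s) are exercised in
## test-acceptance.R only.

smallConfig <- function(seed = 7, ...) {
  cfg <- defaultSyntheticConfig(seed)
  cfg@nTrialsPerClass <- 3
  cfg@stimulusSec <- 6
  cfg
}

smallSession <- local({
  memo <- new.env()
  function(seed = 7) {
    key <- as.character(seed)
    if (is.null(memo[[key]]))
      memo[[key]] <- generateSession(smallConfig(seed))
    memo[[key]]
  }
})

## a raw epoch with given stimulus matrix (channels x samples)
rawEpoch <- function(stimulus, baseline = NULL, fs = 250,
                     label = "fear") {
  nc <- nrow(stimulus)
  chans <- channelNames(standardMontage())[seq_len(nc)]
  if (is.null(baseline)) baseline <- matrix(0, nc, fs)
  new("TrialEpoch", label = label, baseline = baseline,
      stimulus = stimulus, samplingRate = fs, channels = chans,
      processing = character())
}

## mark an epoch as fully preprocessed without touching the data (for
## unit tests that feed analytic signals straight to feature code)
tagPreprocessed <- function(epoch) {
  epoch@processing <- c("baseline", "notch", "bandpass")
  epoch
}

sineMatrix <- function(freqs, fs = 250, seconds = 4, phase = 0) {
  tt <- (seq_len(fs * seconds) - 1) / fs
  t(vapply(freqs, function(f) sin(2 * pi * f * tt + phase),
           numeric(length(tt))))
}
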