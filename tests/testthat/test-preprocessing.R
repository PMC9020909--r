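test_that("baseline correction subtracts the per-channel baseline mean", {
  set.seed(1)
  base <- matrix(rnorm(4 * 250, mean = 3), 4)
  stim <- matrix(rnorm(4 * 1000), 4)
  ep <- rawEpoch(stim, base)
  out <- baselineCorrect(ep)
  expect_equal(out@stimulus, stim - rowMeans(base))
  expect_identical(out@baseline, base)      # baseline kept for audit
  ## stimulus equal to the baseline mean everywhere -> all zero
  flat <- rawEpoch(matrix(rowMeans(base), 4, 100), base)
  expect_true(all(abs(baselineCorrect(flat)@stimulus) < 1e-12))
  ## offset invariance: adding c to one channel's baseline and stimulus
  ## leaves the corrected stimulus unchanged
  ep2 <- rawEpoch(stim, base)
  ep2@baseline[2, ] <- ep2@baseline[2, ] + 5
  ep2@stimulus[2, ] <- ep2@stimulus[2, ] + 5
  expect_equal(baselineCorrect(ep2)@stimulus, out@stimulus)
})

test_that("notch removes 50 Hz and passes 10 Hz", {
  fs <- 250
  tt <- (0:(10 * fs - 1)) / fs
  interior <- (fs + 1):(9 * fs)   # skip filter edge transients
  ep50 <- rawEpoch(matrix(sin(2 * pi * 50 * tt), 1), fs = fs)
  out50 <- notchFilter(ep50)@stimulus[1, interior]
  expect_lt(sqrt(mean(out50^2)), 0.02 * sqrt(0.5))
  ep10 <- rawEpoch(matrix(sin(2 * pi * 10 * tt), 1), fs = fs)
  out10 <- notchFilter(ep10)@stimulus[1, interior]
  expect_equal(sqrt(mean(out10^2)), sqrt(0.5), tolerance = 0.01)
  zero <- rawEpoch(matrix(0, 2, 1000), fs = fs)
  expect_true(all(notchFilter(zero)@stimulus == 0))
})

test_that("broadband bandpass attenuates 100 Hz and DC, passes 10 Hz", {
  fs <- 250
  tt <- (0:(8 * fs - 1)) / fs
  interior <- (fs + 1):(7 * fs)   # skip filter edge transients
  ## amplitude of the f-Hz component over the interior (the filter's
  ## realized frequency response; a 0.1 Hz high-pass edge also rings a
  ## slow startup transient that total RMS would conflate with gain)
  toneAmp <- function(y, f)
    2 * abs(mean(y[interior] * exp(-2i * pi * f * tt[interior])))
  hi <- bandpassFilter(rawEpoch(matrix(sin(2 * pi * 100 * tt), 1)))
  expect_lt(toneAmp(hi@stimulus[1, ], 100), 10^(-20 / 20))
  mid <- bandpassFilter(rawEpoch(matrix(sin(2 * pi * 10 * tt), 1)))
  expect_gt(toneAmp(mid@stimulus[1, ], 10), 10^(-1 / 20))
  dc <- bandpassFilter(rawEpoch(matrix(1, 1, 2000)))
  expect_lt(abs(mean(dc@stimulus[1, ])), 0.05)
  ## invalid design
  expect_error(bandpassFilter(rawEpoch(matrix(0, 1, 100), fs = 100),
                              filterSpec(bandpassHigh = 70)),
               class = "FilterDesignError")
})

test_that("band filters pass in-band tones and reject out-of-band", {
  alpha <- defaultBands()$alpha
  tone10 <- rawEpoch(sineMatrix(10, seconds = 8))
  tone40 <- rawEpoch(sineMatrix(40, seconds = 8))
  rms <- function(m) sqrt(mean(m^2))
  expect_equal(rms(bandFilter(tone10, alpha)@stimulus), sqrt(0.5),
               tolerance = 0.05)
  expect_lt(rms(bandFilter(tone40, alpha)@stimulus) / sqrt(0.5),
            10^(-20 / 20))
  expect_true(all(bandFilter(rawEpoch(matrix(0, 1, 1000)),
                             alpha)@stimulus == 0))
})

test_that("filters are linear and zero-phase", {
  set.seed(42)
  alpha <- defaultBands()$alpha
  x <- matrix(rnorm(2 * 2000), 2)
  y <- matrix(rnorm(2 * 2000), 2)
  fx <- bandFilter(x, alpha, fs = 250)
  fy <- bandFilter(y, alpha, fs = 250)
  fxy <- bandFilter(2 * x + 3 * y, alpha, fs = 250)
  expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-8)
  ## zero-phase: narrowband burst keeps its timing
  tt <- (0:1999) / 250
  burst <- sin(2 * pi * 10 * tt) * exp(-((tt - 4)^2) / 0.5)
  fb <- bandFilter(matrix(burst, 1), alpha, fs = 250)[1, ]
  cc <- ccf(fb, burst, lag.max = 10, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)
})

test_that("pipeline-state tags enforce the fixed preprocessing order", {
  ep <- rawEpoch(matrix(rnorm(2 * 1000), 2))
  pre <- preprocessEpoch(ep)
  expect_identical(pre@processing, c("baseline", "notch", "bandpass"))
  ## going backwards is rejected
  expect_error(baselineCorrect(pre), class = "PipelineOrderError")
  expect_error(notchFilter(pre), class = "PipelineOrderError")
  banded <- bandFilter(pre, defaultBands()$alpha)
  expect_error(bandpassFilter(banded), class = "PipelineOrderError")
  ## feature extraction refuses unpreprocessed epochs
  expect_error(deFeatures(ep), class = "PipelineOrderError")
})

test_that("segmentation tiles the stimulus into half-open windows", {
  ep <- tagPreprocessed(rawEpoch(matrix(rnorm(2 * 7500), 2)))
  segs <- segmentTrial(ep)
  expect_length(segs, 30)
  expect_equal(unique(vapply(segs, function(s) ncol(s@data), 0L)), 250L)
  ## windows partition the signal exactly
  rebuilt <- do.call(cbind, lapply(segs, function(s) s@data))
  expect_identical(rebuilt, ep@stimulus)
  ## 0.5 s step gives floor((30 - 1)/0.5) + 1 = 59 windows
  expect_length(segmentTrial(ep, stepSec = 0.5), 59)
  expect_error(segmentTrial(ep, windowSec = 31), class = "SegmentError")
  expect_error(segmentTrial(ep, stepSec = 0), class = "SegmentError")
  expect_identical(vapply(segs, function(s) s@label, ""),
                   rep("fear", 30))
})
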