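test_that("generation is bit-reproducible from the seed and leaves the RNG alone", {
  cfg <- smallConfig(7)
  set.seed(999); before <- .Random.seed
  s1 <- generateSession(cfg)
  expect_identical(.Random.seed, before)   # no global state consumed
  s2 <- generateSession(cfg)
  expect_identical(sessionData(s1), sessionData(s2))
  expect_identical(eventTable(s1), eventTable(s2))
  s3 <- generateSession(smallConfig(8))
  expect_false(identical(sessionData(s1), sessionData(s3)))
})

test_that("config validation rejects impossible settings", {
  expect_error(syntheticConfig(activation = list(list(
    band = "alpha", channels = "Nope", amplitude = 1, ratio = 2))),
    class = "ConfigError")
  expect_error(syntheticConfig(activation = list(list(
    band = "alpha", channels = "T7", amplitude = 1, ratio = -1))),
    class = "ConfigError")
  expect_error(syntheticConfig(connectivity = list(list(
    pair = c("T7", "T8"), band = "theta", amplitude = 1,
    jitterFear = -0.1, jitterNeutral = 1))), class = "ConfigError")
  expect_error(syntheticConfig(connectivity = list(list(
    pair = "T7", band = "theta", amplitude = 1,
    jitterFear = 0, jitterNeutral = 0))), class = "ConfigError")
  expect_error(syntheticConfig(expressionProb = 0), class = "ConfigError")
  badMix <- matrix(0, 30, 2)
  expect_error(syntheticConfig(spatial = list(band = "beta",
    amplitude = 1, mixingFear = badMix, mixingNeutral = badMix)),
    class = "ConfigError")
})

test_that("ground truth echoes the configured class-information carriers", {
  gt <- groundTruth(defaultSyntheticConfig(1))
  expect_true(all(c("alpha") == unique(gt$activation$band)))
  expect_equal(sort(unique(gt$activation$channel)),
               sort(channelNames(standardMontage())))
  expect_identical(gt$spatial$band, "beta")
  expect_equal(nrow(gt$connectivity), 2 * choose(4, 2))
  expect_true(all(gt$connectivity$band == "theta"))
  ## null config carries no class information anywhere
  gt0 <- groundTruth(nullSyntheticConfig(1))
  expect_equal(nrow(gt0$activation), 0)
  expect_equal(nrow(gt0$spatial), 0)
  expect_equal(nrow(gt0$connectivity), 0)
  ## single coupled group -> its pairs only
  cfg <- syntheticConfig(connectivity = list(list(
    pair = c("T7", "T8"), band = "alpha", amplitude = 1,
    jitterFear = 0, jitterNeutral = 1)))
  expect_equal(nrow(groundTruth(cfg)$connectivity), 1)
})

test_that("background follows a decreasing power law in 2-40 Hz", {
  cfg <- syntheticConfig(seed = 3, nTrialsPerClass = 1,
                         stimulusSec = 8, lineNoiseAmplitude = 0)
  s <- generateSession(cfg)
  x <- sessionData(s)[5, ]
  ## Bartlett-style averaged periodogram to tame chi-squared noise
  segs <- split(x, rep(seq_len(length(x) %/% 250), each = 250))
  pows <- vapply(segs, function(seg)
    computePSD(matrix(seg, 1), fs = 250)@power[1, ], numeric(513))
  pow <- rowMeans(pows)
  freqs <- computePSD(matrix(segs[[1]], 1), fs = 250)@freqs
  sel <- freqs >= 2 & freqs <= 40 & pow > 0
  fitlm <- lm(log(pow[sel]) ~ log(freqs[sel]))
  expect_lt(coef(fitlm)[2], 0)
  expect_gt(summary(fitlm)$r.squared, 0.8)
})

test_that("zero phase jitter yields full coupling on the configured pair", {
  cfg <- syntheticConfig(seed = 12, nTrialsPerClass = 2,
    stimulusSec = 6, noiseScale = 1, lineNoiseAmplitude = 0,
    expressionProb = 1,
    connectivity = list(list(pair = c("T7", "T8"), band = "alpha",
      amplitude = 20, jitterFear = 0, jitterNeutral = 0)))
  s <- generateSession(cfg)
  eps <- lapply(epochSession(s, stimulusSec = 6), preprocessEpoch)
  i <- match(c("T7", "T8"), channelNames(s))
  for (ep in eps[1:2]) {
    mats <- plvMatrices(ep, defaultBands()$alpha)
    plv <- vapply(mats, function(m) m@values[i[1], i[2]], 0)
    expect_true(all(abs(plv - 1) < 0.02))
  }
})

test_that("a no-effect config produces no detectable class effect", {
  ## permutation oracle on trial-mean DE of an effect-free generator
  cfg <- nullSyntheticConfig(19)
  cfg@nTrialsPerClass <- 5
  cfg@stimulusSec <- 6
  s <- generateSession(cfg)
  eps <- epochSession(s, stimulusSec = 6)
  lab <- vapply(eps, trialLabel, "")
  de <- do.call(rbind, lapply(eps, function(e)
    colMeans(deFeatures(preprocessEpoch(e)))))
  stat <- function(l) abs(mean(de[l == "fear", "DE|alpha|T7"]) -
                          mean(de[l == "neutral", "DE|alpha|T7"]))
  obs <- stat(lab)
  perm <- vapply(1:200, function(i) stat(sample(lab)), 0)
  p <- (1 + sum(perm >= obs)) / 201
  expect_gt(p, 0.05)
})

test_that("activation-only data separates DE on affected channels only", {
  cfg <- syntheticConfig(seed = 23, nTrialsPerClass = 6,
    stimulusSec = 6, expressionProb = 1,
    activation = list(list(band = "alpha", channels = c("T7", "T8"),
                           amplitude = 5, ratio = 1.8)))
  s <- generateSession(cfg)
  eps <- epochSession(s, stimulusSec = 6)
  lab <- vapply(eps, trialLabel, "")
  de <- do.call(rbind, lapply(eps, function(e)
    colMeans(deFeatures(preprocessEpoch(e)))))
  d <- function(col) {
    a <- de[lab == "fear", col]; b <- de[lab == "neutral", col]
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }
  expect_gt(d("DE|alpha|T7"), 0.8)
  expect_gt(d("DE|alpha|T8"), 0.8)
  expect_lt(abs(d("DE|beta|Fz")), 0.8)
})

test_that("connectivity-only data separates ENP but not far-channel DE", {
  cfg <- syntheticConfig(seed = 29, nTrialsPerClass = 6,
    stimulusSec = 6, expressionProb = 1,
    connectivity = list(list(pair = c("C3", "C4"), band = "theta",
      amplitude = 8, jitterFear = 0.1, jitterNeutral = 2)))
  s <- generateSession(cfg)
  eps <- epochSession(s, stimulusSec = 6)
  lab <- vapply(eps, trialLabel, "")
  enp <- do.call(rbind, lapply(eps, function(e)
    colMeans(enpFeatures(preprocessEpoch(e)))))
  de <- do.call(rbind, lapply(eps, function(e)
    colMeans(deFeatures(preprocessEpoch(e)))))
  d <- function(m, col) {
    a <- m[lab == "fear", col]; b <- m[lab == "neutral", col]
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }
  expect_gt(d(enp, "ENP|theta|C3-C4"), 0.8)
  far <- paste0("DE|alpha|", c("Fp1", "Fp2", "F7", "F8", "O1", "O2"))
  expect_lt(mean(abs(vapply(far, function(cn) d(de, cn), 0))), 0.8)
})
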