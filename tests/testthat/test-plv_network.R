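test_that("instantaneous phase recovers analytic-signal structure", {
  fs <- 250
  tt <- (0:(4 * fs - 1)) / fs
  alpha <- defaultBands()$alpha
  ph <- instantaneousPhase(matrix(cos(2 * pi * 10 * tt), 1), alpha,
                           fs = fs)
  expect_s4_class(ph, "PhaseSeries")
  v <- ph@values[1, ]
  expect_true(all(v > -pi & v <= pi))
  ## interior unwrapped phase advances at 2*pi*10 rad/s within 1%
  interior <- 101:(length(v) - 100)
  dphi <- diff(v[interior]) %% (2 * pi)
  slope <- mean(dphi) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01)
  ## sin lags cos by pi/2
  ph2 <- instantaneousPhase(rbind(cos(2 * pi * 10 * tt),
                                  sin(2 * pi * 10 * tt)), alpha,
                            fs = fs)
  d <- (ph2@values[1, interior] - ph2@values[2, interior]) %% (2 * pi)
  expect_true(all(abs(d - pi / 2) < 0.05))
  expect_error(instantaneousPhase(matrix(0, 1, 100), alpha, fs = fs),
               class = "ZeroSignalError")
})

test_that("PLV analytic identities hold", {
  set.seed(4)
  fs <- 250
  phi <- runif(5 * fs, -pi, pi)
  ## identical series -> exactly 1 in every window
  expect_identical(unique(plvPair(phi, phi, fs)), 1)
  ## constant phase offset -> exactly 1
  expect_equal(plvPair(phi, phi + 1.234, fs),
               rep(1, length(plvPair(phi, phi, fs))))
  expect_error(plvPair(phi, phi, fs, windowSec = 10),
               class = "WindowError")
})

test_that("independent phases stay below the Rayleigh bound 3/sqrt(N)", {
  set.seed(11)
  N <- 250
  hits <- 0L
  for (i in 1:1000) {
    p1 <- runif(N, -pi, pi); p2 <- runif(N, -pi, pi)
    if (plvPair(p1, p2, fs = N, windowSec = 1, stepSec = 1) <=
          3 / sqrt(N)) hits <- hits + 1L
  }
  expect_gte(hits, 950)
})

test_that("PLV is amplitude-invariant and offset-invariant", {
  set.seed(6)
  fs <- 250
  x <- bandFilter(matrix(rnorm(2 * 4 * fs), 2), defaultBands()$alpha,
                  fs = fs)
  alpha <- defaultBands()$alpha
  p1 <- instantaneousPhase(x, alpha, fs = fs)@values
  p2 <- instantaneousPhase(x * 7.7, alpha, fs = fs)@values
  expect_equal(plvPair(p1[1, ], p1[2, ], fs),
               plvPair(p2[1, ], p2[2, ], fs), tolerance = 1e-10)
  expect_equal(plvPair(p1[1, ] + 0.5, p1[2, ] + 0.5, fs),
               plvPair(p1[1, ], p1[2, ], fs), tolerance = 1e-12)
})

test_that("per-segment PLV matrices are valid and find planted coupling", {
  ## two channels driven by one shared oscillator
  cfg <- syntheticConfig(seed = 31, nTrialsPerClass = 2,
    stimulusSec = 6, noiseScale = 2, expressionProb = 1,
    connectivity = list(list(pair = c("T7", "T8"), band = "alpha",
      amplitude = 12, jitterFear = 0, jitterNeutral = 0)))
  s <- generateSession(cfg)
  ep <- preprocessEpoch(epochSession(s, stimulusSec = 6)[[1]])
  mats <- plvMatrices(ep, defaultBands()$alpha)
  expect_length(mats, 6)
  m <- mats[[3]]@values
  expect_equal(dim(m), c(30, 30))
  expect_equal(max(abs(m - t(m))), 0)
  expect_equal(unname(diag(m)), rep(1, 30))
  expect_true(all(m >= 0 & m <= 1))
  i <- match(c("T7", "T8"), channelNames(s))
  off <- m; diag(off) <- 0
  expect_setequal(as.vector(which(off == max(off), arr.ind = TRUE)[1, ]),
                  i)
  ## zero jitter: the coupled pair's PLV reaches full coupling
  expect_gt(m[i[1], i[2]], 0.98)
})

test_that("ENP feature block is the flattened upper triangle per band", {
  ep <- preprocessEpoch(epochSession(smallSession(), stimulusSec = 6)[[1]])
  enp <- enpFeatures(ep)
  expect_equal(dim(enp), c(6, 435 * 5))
  expect_true(all(enp >= 0 & enp <= 1))
  nm <- colnames(enp)
  expect_identical(nm[1], "ENP|delta|Fp1-Fp2")
  expect_identical(nm[435], "ENP|delta|Pz-Oz")
  expect_identical(nm[436], "ENP|theta|Fp1-Fp2")
  ## consistency with the full PLV matrices
  mats <- plvMatrices(ep, defaultBands()$delta)
  i <- match(c("Fp1", "Fp2"), channelNames(smallSession()))
  expect_equal(unname(enp[3, 1]), mats[[3]]@values[i[1], i[2]])
})

test_that("edge-wise ANOVA matches the squared pooled t statistic", {
  set.seed(17)
  v <- rnorm(12)
  g <- rep(c("fear", "neutral"), each = 6)
  stat <- fearfuse:::.edgeAnova(matrix(v, ncol = 1), g, c("A", "B"),
                                cbind(1L, 2L), defaultBands()$alpha,
                                0.05)
  tt <- t.test(v[g == "fear"], v[g == "neutral"], var.equal = TRUE)
  expect_equal(stat$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(stat$p, tt$p.value, tolerance = 1e-10)
  ## degenerate: identical values -> F = 0, p = 1
  statD <- fearfuse:::.edgeAnova(matrix(rep(1, 12), ncol = 1), g,
                                 c("A", "B"), cbind(1L, 2L),
                                 defaultBands()$alpha, 0.05)
  expect_equal(statD$F, 0)
  expect_equal(statD$p, 1)
})

test_that("connectivity ANOVA flags a strongly coupled pair first", {
  cfg <- syntheticConfig(seed = 41, nTrialsPerClass = 8,
    stimulusSec = 6, noiseScale = 4, expressionProb = 1,
    connectivity = list(list(pair = c("C3", "C4"), band = "alpha",
      amplitude = 10, jitterFear = 0.1, jitterNeutral = 1.5)))
  s <- generateSession(cfg)
  eps <- lapply(epochSession(s, stimulusSec = 6), preprocessEpoch)
  edges <- connectivityAnova(eps, defaultBands()$alpha)
  expect_equal(nrow(edges), 435)
  top <- edges[which.max(edges$F), ]
  expect_setequal(c(top$channel1, top$channel2), c("C3", "C4"))
  expect_true(top$significant)
  ## single-class input is rejected
  expect_error(connectivityAnova(eps[vapply(eps, trialLabel, "") ==
                                       "fear"],
                                 defaultBands()$alpha),
               class = "StatsError")
})

test_that("stronger coupling (smaller jitter) raises mean PLV monotonically", {
  jits <- c(1.5, 1.0, 0.5, 0.1)
  means <- vapply(jits, function(j) {
    vals <- vapply(1:4, function(k) {
      cfg <- syntheticConfig(seed = 50 + k, nTrialsPerClass = 1,
        stimulusSec = 4, noiseScale = 1, expressionProb = 1,
        connectivity = list(list(pair = c("T7", "T8"), band = "alpha",
          amplitude = 12, jitterFear = j, jitterNeutral = j)))
      s <- generateSession(cfg)
      ep <- preprocessEpoch(epochSession(s, stimulusSec = 4)[[1]])
      m <- plvMatrices(ep, defaultBands()$alpha)
      i <- match(c("T7", "T8"), channelNames(s))
      mean(vapply(m, function(x) x@values[i[1], i[2]], 0))
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(means) > 0))
})
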