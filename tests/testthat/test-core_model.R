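test_that("standard montage has the 30 canonical channels, unique and ordered", {
  m <- standardMontage()
  ch <- channelNames(m)
  expect_length(ch, 30)
  expect_false(anyDuplicated(ch) > 0)
  ## all 12 symmetric pairs present
  for (p in list(c("Fp1","Fp2"), c("F7","F8"), c("F3","F4"),
                 c("FT7","FT8"), c("FC3","FC4"), c("T7","T8"),
                 c("P7","P8"), c("C3","C4"), c("TP7","TP8"),
                 c("CP3","CP4"), c("P3","P4"), c("O1","O2")))
    expect_true(all(p %in% ch))
  expect_true(all(c("Fz","FCz","Cz","CPz","Pz","Oz") %in% ch))
})

test_that("default band bank matches the canonical five-band table", {
  b <- defaultBands()
  expect_identical(names(b), c("delta","theta","alpha","beta","gamma"))
  edges <- t(vapply(b, function(x) c(x@low, x@high), numeric(2)))
  expect_equal(unname(edges),
               rbind(c(1,3), c(4,7), c(8,13), c(14,30), c(31,48)))
  expect_error(frequencyBand("bad", 10, 5), "low")
})

test_that("session validity enforces montage consistency and labels", {
  m <- standardMontage()
  d <- matrix(rnorm(30 * 1000), 30)
  s <- EEGSession(d, 250, m, data.frame(onset = 400, label = "fear"))
  expect_s4_class(s, "EEGSession")
  expect_error(EEGSession(d[1:29, ], 250, m,
                          data.frame(onset = 1, label = "fear")))
  expect_error(EEGSession(d, 250, m,
                          data.frame(onset = 1, label = "happy")))
  expect_error(EEGSession(d, 250, m,
                          data.frame(onset = 2000, label = "fear")))
})

test_that("fixture container round-trips bit-exactly", {
  s <- smallSession()
  path <- tempfile(fileext = ".fix")
  writeSession(s, path)
  s2 <- readSession(path, "fixture")
  expect_identical(sessionData(s2), sessionData(s))
  expect_equal(eventTable(s2), eventTable(s))
  expect_identical(samplingRate(s2), samplingRate(s))
})

test_that("default synthetic session has 40 events, 20 per class", {
  cfg <- defaultSyntheticConfig(seed = 11)
  cfg@stimulusSec <- 2          # layout only; keep the test light
  s <- generateSession(cfg)
  tab <- table(eventTable(s)$label)
  expect_equal(unname(tab[["fear"]]), 20)
  expect_equal(unname(tab[["neutral"]]), 20)
  expect_equal(nrow(eventTable(s)), 40)
})

test_that("epoching cuts 1 s baseline + stimulus at the onset, half-open", {
  m <- standardMontage()
  d <- matrix(seq_len(30 * 8100), 30)  # distinguishable values
  s <- EEGSession(d, 250, m, data.frame(onset = 250, label = "neutral"))
  ep <- epochSession(s, stimulusSec = 30)[[1]]
  ## onset at sample 250 (0-based): baseline covers [0, 250),
  ## stimulus [250, 7750)
  expect_equal(ep@baseline, sessionData(s)[, 1:250])
  expect_equal(dim(ep@stimulus), c(30, 7500))
  expect_equal(unname(ep@stimulus[1, 1]), d[1, 251])
  expect_equal(unname(ep@stimulus[1, 7500]), d[1, 7750])
  expect_identical(trialLabel(ep), "neutral")
})

test_that("epoching is label- and count-preserving and bounds-checked", {
  s <- smallSession()
  eps <- epochSession(s, stimulusSec = 6)
  expect_length(eps, nrow(eventTable(s)))
  expect_equal(table(vapply(eps, trialLabel, "")),
               table(as.character(eventTable(s)$label)))
  ## channel order is preserved at every stage boundary
  expect_identical(channelNames(eps[[1]]), channelNames(s))
  ## an onset < 1 s from the record start cannot be epoched
  m <- standardMontage()
  bad <- EEGSession(matrix(0, 30, 10000), 250, m,
                    data.frame(onset = 100, label = "fear"))
  expect_error(epochSession(bad, stimulusSec = 30),
               class = "EpochBoundsError")
  noEv <- EEGSession(matrix(0, 30, 10000), 250, m)
  expect_error(epochSession(noEv), class = "EventError")
})

test_that("EDF files written by the package re-read to the same session", {
  cfg <- smallConfig(5)
  cfg@stimulusSec <- 2
  s <- generateSession(cfg)
  path <- tempfile(fileext = ".edf")
  writeEDF(s, path)
  s2 <- readSession(path, "edf")
  expect_equal(channelNames(s2), channelNames(s))
  expect_equal(dim(sessionData(s2)), dim(sessionData(s)))
  ## 16-bit quantization: worst case one digital step per channel
  step <- apply(sessionData(s), 1, function(x)
    (max(x) - min(x)) / 65535)
  err <- abs(sessionData(s2) - sessionData(s))
  expect_true(all(err <= 1.01 * step + 0.01))
  expect_equal(eventTable(s2)$onset, eventTable(s)$onset)
  expect_equal(as.character(eventTable(s2)$label),
               as.character(eventTable(s)$label))
})

test_that("EDF reader drops non-EEG channels by name and flags problems", {
  cfg <- smallConfig(6); cfg@stimulusSec <- 2
  s <- generateSession(cfg)
  path <- tempfile(fileext = ".edf")
  writeEDF(s, path)
  ## missing sidecar -> EventError
  file.remove(paste0(path, ".events"))
  expect_error(readSession(path, "edf"), class = "EventError")
  ## wrong expected rate -> resampling refused
  writeEDF(s, path)
  expect_error(readSession(path, "edf", samplingRate = 500),
               class = "ResampleNotSupportedError")
})

test_that("pipeline configs load from JSON with sensible fallbacks", {
  path <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    bands = list(list(name = "slow", low = 1, high = 8),
                 list(name = "fast", low = 20, high = 45)),
    filters = list(notchFreq = 60)), auto_unbox = TRUE), path)
  cfg <- readPipelineConfig(path)
  expect_identical(names(cfg$bands), c("slow", "fast"))
  expect_equal(cfg$bands$fast@high, 45)
  expect_equal(cfg$filters@notchFreq, 60)
  expect_equal(cfg$filters@bandpassOrder, 10)     # fallback
  expect_identical(channelNames(cfg$montage),
                   channelNames(standardMontage()))
  expect_error(readPipelineConfig("no-such-file.yaml"),
               class = "FileError")
})
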