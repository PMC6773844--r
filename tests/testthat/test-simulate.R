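test_that("window-table row counts follow block durations", {
  lay <- buildLayout(3)
  des <- oneBlockDesign(duration_s = 300)
  tab <- simulateWindowTable(des, lay, simulationParams(seed = 1),
                             bands = bandDef("alpha", 9.5, 11.5))
  # one 300-s block -> 10 windows per channel per band
  expect_equal(nrow(tab), 10 * 3 * 1)
  expect_equal(sort(unique(tab$window_index)), 1:10)
  # 299-s block drops the trailing partial window
  tab2 <- simulateWindowTable(oneBlockDesign(299), lay,
                              simulationParams(seed = 1),
                              bands = bandDef("alpha", 9.5, 11.5))
  expect_equal(max(tab2$window_index), 9)
})

test_that("identical seeds reproduce bit-identical outputs", {
  p <- presetEmulationSmall(effectSize = 0.5, seed = 42)
  t1 <- simulateWindowTable(p$design, p$layout, p$params)
  t2 <- simulateWindowTable(p$design, p$layout, p$params)
  expect_identical(t1, t2)
  r1 <- simulateRecording(p$design, p$layout, p$params, "P2",
                          bands = p$bands)
  r2 <- simulateRecording(p$design, p$layout, p$params, "P2",
                          bands = p$bands)
  expect_identical(r1@samples, r2@samples)
  expect_identical(r1@artifactAnnotations, r2@artifactAnnotations)
})

test_that("between-participant variance of participant means recovers participantSd^2", {
  lay <- buildLayout(2)
  des <- twoBlockDesign(nParticipants = 5, duration_s = 300)
  band <- bandDef("alpha", 9.5, 11.5)
  vars <- vapply(1:100, function(i) {
    par <- simulationParams(participantSd = 1, windowNoiseSd = 0.5,
                            seed = 5000 + i)
    tab <- simulateWindowTable(des, lay, par, bands = band)
    tab <- tab[tab$channel == "E1", ]
    var(tapply(tab$power, tab$participant, mean))
  }, numeric(1))
  # E[var of participant means] = participantSd^2 + windowNoiseSd^2 / n_win
  nWin <- 2 * 10
  expected <- 1 + 0.25 / nWin
  mcSE <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - expected), 3 * mcSE)
})

test_that("zero artifact rate yields zero artifact annotations", {
  p <- presetEmulationSmall(seed = 3, blockDuration = 60)
  par <- simulationParams(artifactRate = 0, seed = 3)
  rec <- simulateRecording(p$design, p$layout, par, "P1")
  expect_equal(nrow(rec@artifactAnnotations), 0)
})

test_that("null simulation carries no condition contrast", {
  lay <- buildLayout(4)
  des <- twoBlockDesign(nParticipants = 2, duration_s = 240)
  par <- simulationParams(participantSd = 0, windowNoiseSd = 0.3,
                          artifactRate = 0,
                          bandEffects = bandEffect("alpha", 0), seed = 8)
  band <- bandDef("alpha", 9.5, 11.5)
  rec <- simulateRecording(des, lay, par, "P1", bands = band)
  w <- segmentWindows(rec)
  fs <- samplingRate(rec)
  vals <- sapply(seq_len(nrow(w)), function(i) {
    idx <- round(w$onset_s[i] * fs) + seq_len(round(30 * fs))
    ps <- welchPsd(rec@samples[, idx, drop = FALSE], fs)
    eegperm:::bandTotalLogPower(ps$psd, band, ps$freq)
  })
  contrast <- mean(vals[, w$memory == "NDE"]) -
    mean(vals[, w$memory == "AUTOBIO"])
  n1 <- sum(w$memory == "NDE") * nrow(vals)
  mcSE <- 0.3 * sqrt(2 / n1)
  expect_lt(abs(contrast), 3 * mcSE)
})

test_that("an injected alpha shift is recovered from the synthesised signal", {
  lay <- buildLayout(6)
  patch <- frontalChannels(lay, 3)
  des <- twoBlockDesign(nParticipants = 1, duration_s = 1560)
  par <- simulationParams(
    bandEffects = bandEffect("alpha", 0.5, memory = "NDE",
                             channels = patch),
    participantSd = 0, artifactRate = 0, seed = 21)
  band <- bandDef("alpha", 9.5, 11.5)
  rec <- simulateRecording(des, lay, par, "P1", bands = band)
  w <- segmentWindows(rec) # 52 windows x 2 blocks
  fs <- samplingRate(rec)
  vals <- sapply(seq_len(nrow(w)), function(i) {
    idx <- round(w$onset_s[i] * fs) + seq_len(round(30 * fs))
    ps <- welchPsd(rec@samples[, idx, drop = FALSE], fs)
    eegperm:::bandTotalLogPower(ps$psd, band, ps$freq)
  })
  rownames(vals) <- channelLabels(rec)
  nde <- vals[patch, w$memory == "NDE", drop = FALSE]
  aut <- vals[patch, w$memory == "AUTOBIO", drop = FALSE]
  contrast <- mean(nde) - mean(aut)
  mcSE <- sqrt(var(as.numeric(nde)) / length(nde) +
                 var(as.numeric(aut)) / length(aut))
  # 95% Monte-Carlo interval around the injected 0.5
  expect_lt(abs(contrast - 0.5), 1.96 * mcSE + 0.02)
})

test_that("misconfigured effects are rejected", {
  lay <- buildLayout(4)
  expect_error(
    simulationParams(bandEffects = bandEffect("alpha", 1, state = "XX")),
    "unknown factor level")
  par <- simulationParams(
    bandEffects = bandEffect("alpha", 1, channels = "E99"))
  expect_error(simulateWindowTable(oneBlockDesign(60), lay, par),
               "configuration error")
})
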