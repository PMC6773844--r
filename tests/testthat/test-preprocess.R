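fs <- 250

sineRecording <- function(freqHz, durS = 80, fs = 250) {
  t <- seq_len(durS * fs) / fs
  recording(matrix(sin(2 * pi * freqHz * t), 1), fs)
}

midAmplitude <- function(rec) {
  n <- ncol(rec@samples)
  max(abs(rec@samples[1, round(n * 0.4):round(n * 0.6)]))
}

test_that("high-pass removes DC and passes 10 Hz within the transfer-function prediction", {
  # constant input decays toward zero
  dc <- recording(matrix(1, 1, 5000), fs)
  out <- highpass(dc, 0.1)
  expect_lt(max(abs(out@samples[1, 2000:3000])), 0.02)

  bf <- signal::butter(1, 0.1 / (fs / 2), "high")
  # 10 Hz passes nearly untouched
  r10 <- highpass(sineRecording(10), 0.1)
  expect_lt(abs(midAmplitude(r10) - 1), 0.01)
  expect_lt(abs(midAmplitude(r10) - eegperm:::filterGain(bf, 10, fs)^2),
            0.01)

  # 0.01 Hz is attenuated at least as much as one filter pass predicts
  slow <- sineRecording(0.01, durS = 400)
  rs <- highpass(slow, 0.1)
  predicted <- eegperm:::filterGain(bf, 0.01, fs)
  expect_lt(max(abs(rs@samples[1, ])), predicted * 1.05)
})

test_that("band-stop attenuates 50 Hz and leaves 10 Hz intact", {
  bf <- signal::butter(2, c(48, 52) / (fs / 2), "stop")
  r50 <- lineNoiseFilter(sineRecording(50))
  predicted <- eegperm:::filterGain(bf, 50, fs)
  expect_lt(midAmplitude(r50), predicted + 0.1)
  expect_lt(midAmplitude(r50), 0.1)

  r10 <- lineNoiseFilter(sineRecording(10))
  expect_lt(abs(midAmplitude(r10) - 1), 0.02)

  z <- recording(matrix(0, 2, 1000), fs)
  expect_equal(lineNoiseFilter(z)@samples, z@samples)

  expect_error(lineNoiseFilter(sineRecording(10), 52, 48),
               "invalid filter")
  expect_error(highpass(sineRecording(10), 200), "invalid filter")
})

test_that("filters are linear and leave annotations untouched", {
  set.seed(1)
  x <- matrix(rnorm(2 * 2000), 2)
  y <- matrix(rnorm(2 * 2000), 2)
  ann <- data.frame(onset_s = 1, duration_s = 2, state = "NC",
                    memory = "NDE", phase = "OBE")
  mk <- function(m) recording(m, fs, conditionAnnotations = ann,
                              artifactAnnotations = data.frame(
                                onset_s = 0.5, duration_s = 0.25))
  for (f in list(function(r) highpass(r, 0.5),
                 function(r) lineNoiseFilter(r))) {
    lhs <- f(mk(2 * x + 3 * y))@samples
    rhs <- 2 * f(mk(x))@samples + 3 * f(mk(y))@samples
    expect_lt(max(abs(lhs - rhs)), 1e-8)
    expect_identical(f(mk(x))@conditionAnnotations, ann)
    expect_equal(f(mk(x))@artifactAnnotations$onset_s, 0.5)
  }
})

test_that("spherical splines reconstruct a smooth field at a bad sensor", {
  lay <- buildLayout(32)
  pos <- channelPositions(lay)
  pos <- pos / sqrt(rowSums(pos^2))
  field <- 0.5 + pos[, 1] + 2 * pos[, 2] + pos[, 3]^2
  X <- matrix(rep(field, 20), ncol = 20,
              dimnames = list(channelLabels(lay), NULL))
  rec <- recording(X, fs, badChannels = "E5")
  out <- interpolateBadChannels(rec, lay)
  expect_lt(abs(out@samples["E5", 1] - field["E5"]) / abs(field["E5"]),
            0.05)
  expect_length(out@badChannels, 0)
  # untouched channels pass through
  expect_equal(out@samples["E1", ], X["E1", ])
})

test_that("interpolation handles the worst-case bad-channel load but refuses a majority", {
  lay <- buildLayout(257)
  X <- matrix(rnorm(257 * 10), 257,
              dimnames = list(channelLabels(lay), NULL))
  rec <- recording(X, fs, badChannels = channelLabels(lay)[1:64])
  expect_s4_class(interpolateBadChannels(rec, lay), "Recording")
  recBad <- recording(X, fs, badChannels = channelLabels(lay)[1:129])
  expect_error(interpolateBadChannels(recBad, lay), "50%")
  # no bad channels: identity
  recOk <- recording(X, fs)
  expect_identical(interpolateBadChannels(recOk, lay), recOk)
})

test_that("average reference zeroes the channel mean, is idempotent, and recuperates the reference channel", {
  set.seed(2)
  X <- matrix(rnorm(256 * 100), 256)
  rec <- recording(X, fs)
  out <- averageReference(rec, referenceLabel = "Cz")
  expect_equal(nrow(out@samples), 257)
  expect_lt(max(abs(colMeans(out@samples))), 1e-9)
  expect_equal(out@reference, "average")
  out2 <- averageReference(out, referenceLabel = "Cz")
  expect_equal(nrow(out2@samples), 257)
  expect_equal(out2@samples, out@samples, tolerance = 1e-12)
  expect_error(averageReference(recording(matrix(1, 1, 10), fs)),
               "invalid montage")
})

test_that("cropping to condition blocks shifts annotations onto the new time base", {
  X <- matrix(seq_len(2 * 250 * 30), 2, byrow = TRUE)
  ann <- data.frame(onset_s = c(5, 20), duration_s = c(5, 5),
                    state = "NC", memory = c("NDE", "AUTOBIO"),
                    phase = c("OBE", "KS"))
  art <- data.frame(onset_s = c(6, 12), duration_s = c(1, 2))
  rec <- recording(X, 250, conditionAnnotations = ann,
                   artifactAnnotations = art)
  out <- cropToConditions(rec)
  expect_equal(ncol(out@samples), 10 * 250)
  expect_equal(out@conditionAnnotations$onset_s, c(0, 5))
  # artifact at 6 s lies inside block 1 (5..10) -> onset 1; 12 s is dropped
  expect_equal(out@artifactAnnotations$onset_s, 1)
})
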