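mkRec <- function(durS, fs = 250, nCh = 1) {
  ann <- data.frame(onset_s = 0, duration_s = durS, state = "NC",
                    memory = "NDE", phase = "OBE")
  recording(matrix(rnorm(nCh * durS * fs), nCh), fs,
            conditionAnnotations = ann)
}

test_that("segmentation floors to whole windows per block", {
  expect_equal(nrow(segmentWindows(mkRec(300))), 10)
  expect_equal(nrow(segmentWindows(mkRec(299))), 9)
  expect_equal(nrow(segmentWindows(mkRec(1200))), 40)
  expect_warning(w <- segmentWindows(mkRec(20)), "shorter")
  expect_equal(nrow(w), 0)
})

test_that("windows are rejected only above 5 s of artifact overlap", {
  rec <- mkRec(90)
  w <- segmentWindows(rec)
  art <- data.frame(onset_s = c(10, 40), duration_s = c(5, 5.2))
  out <- rejectArtifactWindows(w, art)
  expect_true(out$retained[1])   # exactly 5.0 s -> retained
  expect_false(out$retained[2])  # 5.2 s -> rejected
  expect_true(out$retained[3])
  # conservation: retained + rejected = segmented
  expect_equal(sum(out$retained) + sum(!out$retained), nrow(w))
  # no artifacts -> everything retained
  all_in <- rejectArtifactWindows(w, emptyArtifactAnnotations())
  expect_true(all(all_in$retained))
})

test_that("Welch PSD matches the sinusoid and white-noise power oracles", {
  fs <- 250
  t <- seq_len(30 * fs) / fs
  w <- welchPsd(sin(2 * pi * 10 * t), fs)
  expect_equal(w$freq[2] - w$freq[1], 1) # 1 Hz bins
  expect_equal(w$freq[which.max(w$psd[1, ])], 10)
  inBand <- w$freq >= 8 & w$freq <= 12
  expect_lt(abs(sum(w$psd[1, inBand]) - 0.5) / 0.5, 0.05)
  expect_lt(sum(w$psd[1, !inBand]) / 0.5, 0.01)

  # white noise: integrated power recovers the variance (100 draws)
  set.seed(4)
  tot <- vapply(1:100, function(i) {
    ww <- welchPsd(rnorm(10 * fs, sd = 2), fs)
    sum(ww$psd[1, ]) * (ww$freq[2] - ww$freq[1])
  }, numeric(1))
  expect_lt(abs(mean(tot) - 4), 3 * sd(tot) / sqrt(100))

  expect_equal(max(welchPsd(rep(0, 1000), fs)$psd), 0)
  expect_error(welchPsd(rnorm(100), fs, segS = 1), "segment longer")
})

test_that("band power is the RMS of log power over band bins", {
  freq <- 1:4
  psd <- matrix(exp(c(1, 2, 2, 1)), 1)
  expect_equal(unname(bandPower(psd, bandDef("b", 1, 4), freq = freq)),
               sqrt(10 / 4))
  # constant log power c -> |c|
  psdC <- matrix(exp(-3), 1, 4)
  expect_equal(unname(bandPower(psdC, bandDef("b", 1, 4), freq = freq)), 3)
  # single-bin band with power p -> |log p|
  expect_equal(unname(bandPower(matrix(5, 1, 4), bandDef("b", 1.5, 2.5),
                                freq = freq)), log(5))
  expect_error(bandPower(matrix(0, 1, 4), bandDef("b", 1, 4), freq = freq),
               "non-positive")
  expect_silent(bandPower(matrix(0, 1, 4), bandDef("b", 1, 4), freq = freq,
                          floor = 1e-12))
})

test_that("band power is invariant to channel order and window permutation", {
  fs <- 250
  set.seed(9)
  X <- matrix(rnorm(4 * 30 * fs), 4)
  rownames(X) <- paste0("E", 1:4)
  ps <- welchPsd(X, fs)
  bp <- bandPower(ps, bandDef("alpha", 9.5, 11.5), floor = 1e-12)
  perm <- c(3, 1, 4, 2)
  ps2 <- welchPsd(X[perm, ], fs)
  bp2 <- bandPower(ps2, bandDef("alpha", 9.5, 11.5), floor = 1e-12)
  expect_equal(bp2, bp[perm])
})

test_that("the specific-band difference subtracts matched rows", {
  p <- presetEmulationSmall(seed = 6, nChannels = 3, blockDuration = 60)
  tab <- simulateWindowTable(p$design, p$layout, p$params,
                             bands = bandPresets("narrow"))
  d <- bandDifference(tab, "alpha", "theta")
  expect_true(all(d$band == "specific_alpha"))
  a <- tab[tab$band == "alpha", ]
  t2 <- tab[tab$band == "theta", ]
  expect_equal(d$power, a$power - t2$power)
  # antisymmetry
  d2 <- bandDifference(tab, "theta", "alpha")
  expect_equal(d2$power, -d$power)
  # identical bands -> all-zero difference
  same <- tab[tab$band == "alpha", ]
  same$band <- "theta"
  d3 <- bandDifference(rbind(tab[tab$band == "alpha", ], same),
                       "alpha", "theta")
  expect_true(all(d3$power == 0))
  expect_error(bandDifference(tab[tab$band == "alpha", ], "alpha", "theta"),
               "alignment error")
})

test_that("band proposal flags spectral bumps and stays silent on pure 1/f", {
  f <- 1:30
  bg <- 10 * f^-1
  expect_equal(nrow(proposeBands(list(mid = bg), f)), 0)
  one <- proposeBands(list(mid = bg + 5 * exp(-(f - 10)^2)), f)
  expect_equal(nrow(one), 1)
  expect_true(one$lo[1] <= 10 && one$hi[1] >= 10)
  three <- proposeBands(list(mid = bg + 5 * exp(-2 * (f - 2)^2) +
                               5 * exp(-2 * (f - 10)^2) +
                               2 * exp(-2 * (f - 18)^2)), f)
  expect_equal(nrow(three), 3)
  expect_true(all(diff(three$lo) > 0) && all(three$hi[-3] < three$lo[-1]))
  expect_error(proposeBands(list(mid = bg - 1), f), "non-positive")
})

test_that("the window table pipeline conserves window accounting", {
  p <- presetEmulationSmall(seed = 13, nChannels = 4, blockDuration = 60)
  par <- simulationParams(artifactRate = 8, artifactMeanDuration = 6,
                          seed = 13)
  rec <- simulateRecording(p$design, p$layout, par, "P1")
  tab <- computeWindowTable(rec, bands = p$bands, design = p$design)
  expect_equal(attr(tab, "n_segmented"),
               attr(tab, "n_retained") + attr(tab, "n_rejected"))
  expect_gt(attr(tab, "n_rejected"), 0)
  expect_equal(nrow(tab),
               attr(tab, "n_retained") * 4 * nrow(p$bands))
  expect_true(all(is.finite(tab$power)))
  expect_equal(unique(tab$age), 60)
})
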