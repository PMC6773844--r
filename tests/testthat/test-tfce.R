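test_that("TFCE basics: zero maps, isolated peaks, oracle equality", {
  lay <- buildLayout(6)
  labels <- channelLabels(lay)
  z <- setNames(rep(0, 6), labels)
  expect_equal(unname(tfceTransform(z, lay)), rep(0, 6))

  # isolated suprathreshold channel integrates to T^(H+1)/(H+1)
  v <- setNames(c(4, 0, 0, 0, 0, 0), labels)
  enh <- tfceTransform(v, lay, tfceParams(E = 1, H = 2, nSteps = 1000))
  expect_lt(abs(enh[[1]] - 4^3 / 3) / (4^3 / 3), 0.01)

  # matches the brute-force threshold-loop oracle on an arbitrary map
  set.seed(3)
  v2 <- setNames(rnorm(6, sd = 2), labels)
  pr <- tfceParams(nSteps = 60)
  expect_equal(unname(tfceTransform(v2, lay, pr)),
               unname(tfceOracle(v2[labels], adjacencyEdges(lay),
                                 pr$E, pr$H, pr$nSteps)),
               tolerance = 1e-12)
  expect_error(tfceTransform(setNames(rnorm(6), paste0("X", 1:6)), lay),
               "alignment error")
})

test_that("raising a channel statistic never decreases any enhanced value", {
  # raise a non-maximal channel: the integration grid is unchanged, so the
  # discrete transform must be exactly monotone
  for (i in 1:25) {
    g <- randomGraphMap(8, seed = 100 + i)
    pr <- tfceParams(nSteps = 40)
    v <- pmax(g$values, 0)
    base <- tfceTransform(v, g$layout, pr)
    j <- sample(which(v < max(v)), 1)
    up <- v
    up[j] <- runif(1, v[j], max(v))
    raised <- tfceTransform(up, g$layout, pr)
    expect_true(all(raised >= base - 1e-9))
  }
  # raising the global maximum rescales the finite grid; monotonicity then
  # holds up to the discretisation error, which shrinks with nSteps
  g <- randomGraphMap(8, seed = 321)
  v <- pmax(g$values, 0)
  pr <- tfceParams(nSteps = 2000)
  base <- tfceTransform(v, g$layout, pr)
  up <- v
  up[which.max(v)] <- max(v) * 1.3
  raised <- tfceTransform(up, g$layout, pr)
  expect_true(all(raised >= base - 0.002 * max(base)))
})

test_that("permutation p-values follow the add-one estimator", {
  nullMax <- seq_len(2200)
  expect_equal(unname(channelPvalues(c(a = 3000), nullMax)), 1 / 2201)
  expect_equal(unname(channelPvalues(c(a = 0.5), nullMax)), 1)
  p <- channelPvalues(c(a = 7, b = 7), nullMax)
  expect_equal(p[["a"]], p[["b"]])
  # monotone non-increasing in the observed value
  obs <- sort(runif(10, 0, 2500))
  pv <- channelPvalues(setNames(obs, paste0("c", 1:10)), nullMax)
  expect_true(all(diff(pv) <= 0))
})

test_that("the permutation null is reproducible and enumerates tiny designs", {
  lay <- buildLayout(4)
  des <- twoBlockDesign(nParticipants = 5, duration_s = 120)
  par <- simulationParams(seed = 71)
  tab <- simulateWindowTable(des, lay, par,
                             bands = bandDef("alpha", 9.5, 11.5))
  spec <- modelSpec("memory")
  sch <- permutationScheme(nPermutations = 100, seed = 4)
  # 2 blocks x 5 participants -> 2^5 = 32 distinct relabelings
  expect_warning(nm <- buildNull(tab, "alpha", spec, lay,
                                 tfceParams(nSteps = 30), sch),
                 "exhaustively")
  expect_equal(nrow(nm), 32)
  expect_true(isTRUE(attr(nm, "exhaustive")))

  # same seed -> identical null vectors (random sampling regime)
  des8 <- designEmulation(blockDuration = 60)
  tab8 <- simulateWindowTable(des8, lay, par,
                              bands = bandDef("alpha", 9.5, 11.5))
  n1 <- buildNull(tab8, "alpha", spec, lay, tfceParams(nSteps = 30), sch)
  n2 <- buildNull(tab8, "alpha", spec, lay, tfceParams(nSteps = 30), sch)
  expect_identical(n1, n2)
  expect_error(buildNull(tab8, "alpha", modelSpec("state"), lay,
                         tfceParams(), sch),
               "not part of the model")
})

test_that("significance summaries report clusters and peaks over adjacency", {
  lay <- buildLayout(10)
  labels <- channelLabels(lay)
  pv <- setNames(rep(0.5, 10), labels)
  tv <- setNames(rep(0, 10), labels)
  s0 <- significanceSummary(pv, tv, lay, 0.05)
  expect_equal(s0$n_significant, 0)
  expect_length(s0$clusters, 0)

  # an effect on a connected frontal patch is reported as one cluster
  patch <- frontalChannels(lay, 3)
  pv[patch] <- 0.001
  tv[patch] <- c(5, 7, 6)
  s1 <- significanceSummary(pv, tv, lay, 0.016)
  expect_setequal(s1$significant, patch)
  expect_true(any(vapply(s1$clusters, function(cl)
    all(patch %in% cl), logical(1))))
  expect_equal(s1$peak_channel, patch[2])
  expect_equal(s1$peak_T, 7)
  expect_error(significanceSummary(pv, tv, lay, 1.5), "threshold")
})

test_that("a strong injected patch effect is detected end to end", {
  p <- presetEmulationSmall(effectSize = 1.2, seed = 23)
  tab <- simulateWindowTable(p$design, p$layout, p$params,
                             bands = bandDef("alpha", 9.5, 11.5))
  res <- permutationTest(tab, "alpha", modelSpec("memory"), p$layout,
                         tfceParams(nSteps = 50),
                         permutationScheme(nPermutations = 200, seed = 9),
                         threshold = bandThreshold(0.05, 3))
  expect_gt(res@summary$n_significant, 0)
  expect_true(res@summary$peak_channel %in% p$effectChannels)
  expect_true(all(res@pvalues > 0 & res@pvalues <= 1))
  # monotone: enhanced statistic order matches p-value order (reversed)
  ord <- order(abs(res@enhanced), decreasing = TRUE)
  expect_true(all(diff(res@pvalues[ord]) >= 0))
})
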