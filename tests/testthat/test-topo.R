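simTable <- function(effectSize, seed, nChannels = 2, duration = 120,
                     channels = NULL) {
  lay <- buildLayout(nChannels)
  des <- designEmulation(blockDuration = duration)
  eff <- if (effectSize != 0)
    bandEffect("alpha", effectSize, memory = "NDE", channels = channels)
  else emptyBandEffects()
  par <- simulationParams(bandEffects = eff, seed = seed)
  list(tab = simulateWindowTable(des, lay, par,
                                 bands = bandDef("alpha", 9.5, 11.5)),
       layout = lay)
}

test_that("profile and lmer engines agree on the same model", {
  s <- simTable(0.4, seed = 31)
  spec <- modelSpec(c("state", "memory", "focus", "age", "shss"))
  fp <- fitChannel(s$tab, "E1", "alpha", spec, engine = "profile")
  fl <- fitChannel(s$tab, "E1", "alpha", spec, engine = "lmer")
  expect_equal(fp@logLik, fl@logLik, tolerance = 1e-6)
  expect_equal(fp@AIC, fl@AIC, tolerance = 1e-6)
  expect_equal(fp@coefficients$estimate, fl@coefficients$estimate,
               tolerance = 1e-5)
  expect_equal(fp@coefficients$t, fl@coefficients$t, tolerance = 1e-4)
  expect_equal(fp@effectTests$chisq, fl@effectTests$chisq,
               tolerance = 1e-4)
})

test_that("null fits produce calibrated likelihood-ratio p-values", {
  pvals <- vapply(1:200, function(i) {
    s <- simTable(0, seed = 9000 + i)
    fit <- fitChannel(s$tab, "E1", "alpha", modelSpec("memory"))
    fit@effectTests$p[fit@effectTests$term == "memory"]
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("an injected condition shift is recovered by the mixed model", {
  s <- simTable(0.5, seed = 77, duration = 300)
  fit <- fitChannel(s$tab, "E1", "alpha", modelSpec("memory"))
  co <- fit@coefficients[fit@coefficients$term == "memoryNDE", ]
  expect_lt(abs(co$estimate - 0.5), 3 * co$se)
  # LRT agrees in direction
  expect_lt(effectTest(fit, "memory")$p, 0.05)
})

test_that("degenerate designs and inputs raise errors", {
  lay <- buildLayout(2)
  des <- oneBlockDesign(duration_s = 120) # one participant
  tab <- simulateWindowTable(des, lay, simulationParams(seed = 1),
                             bands = bandDef("alpha", 9.5, 11.5))
  expect_error(fitChannel(tab, "E1", "alpha", modelSpec(character())),
               "participant")
  s <- simTable(0, seed = 5)
  s$tab$power <- 1
  expect_error(fitChannel(s$tab, "E1", "alpha", modelSpec("memory")),
               "zero-variance")
  expect_error(fitAllChannels(s$tab, "alpha", modelSpec("memory")),
               "zero-variance")
  f <- fitChannel(simTable(0, seed = 6)$tab, "E1", "alpha",
                  modelSpec("memory"))
  expect_error(effectTest(f, "state"), "invalid request")
  expect_error(modelSpec("state:memory"), "lower-order")
})

test_that("AIC ladder selection finds the generating model", {
  lay <- buildLayout(2)
  des <- designEmulation(blockDuration = 300)
  eff <- rbind(bandEffect("alpha", 1.0, memory = "NDE"),
               bandEffect("alpha", 0.8, state = "HY"),
               bandEffect("alpha", 0.6, phase = "PE"),
               bandEffect("alpha", 1.2, state = "HY", memory = "NDE",
                          phase = "PE"))
  par <- simulationParams(bandEffects = eff, windowNoiseSd = 0.3,
                          seed = 11)
  tab <- simulateWindowTable(des, lay, par,
                             bands = bandDef("alpha", 9.5, 11.5))
  sel <- selectModel(tab, "E1", "alpha")
  expect_true("state:memory:focus" %in% sel@fixedTerms)

  nullTab <- simTable(0, seed = 12, duration = 300)$tab
  sel0 <- selectModel(nullTab, "E1", "alpha")
  expect_length(sel0@fixedTerms, 0)

  # exact AIC tie resolves to the simpler (earlier) candidate
  ladder <- list(modelSpec("memory"), modelSpec("memory"))
  tie <- selectModel(nullTab, "E1", "alpha", ladder = ladder)
  expect_true(attr(tie, "aicTable")$selected[1])
})

test_that("channel maps localise effects and respect channel independence", {
  lay <- buildLayout(16)
  patch <- frontalChannels(lay, 4)
  des <- designEmulation(blockDuration = 120)
  par <- simulationParams(
    bandEffects = bandEffect("alpha", 1.5, memory = "NDE",
                             channels = patch),
    windowNoiseSd = 0.3, seed = 19)
  tab <- simulateWindowTable(des, lay, par,
                             bands = bandDef("alpha", 9.5, 11.5))
  spec <- modelSpec("memory")
  maps <- fitAllChannels(tab, "alpha", spec)
  tv <- maps$memoryNDE@statistic
  expect_setequal(names(sort(abs(tv), decreasing = TRUE))[1:4], patch)

  # permuting the channel labels permutes the maps identically
  relabel <- setNames(channelLabels(lay),
                      sample(channelLabels(lay)))
  tab2 <- tab
  tab2$channel <- names(relabel)[match(tab$channel, relabel)]
  maps2 <- fitAllChannels(tab2, "alpha", spec)
  tv2 <- maps2$memoryNDE@statistic
  expect_equal(unname(tv2[names(relabel)[match(names(tv), relabel)]]),
               unname(tv))

  # row order of the table is irrelevant (maps indexed by channel name)
  tab3 <- tab[sample(nrow(tab)), ]
  maps3 <- fitAllChannels(tab3, "alpha", spec)
  expect_equal(maps3$memoryNDE@statistic[names(tv)], tv,
               tolerance = 1e-8)
})

test_that("null channel T-statistics are symmetric about zero", {
  tstats <- vapply(1:150, function(i) {
    s <- simTable(0, seed = 4000 + i)
    maps <- fitAllChannels(s$tab, "alpha", modelSpec("memory"))
    unname(maps$memoryNDE@statistic["E1"])
  }, numeric(1))
  expect_lt(abs(mean(tstats)), 3 * sd(tstats) / sqrt(length(tstats)))
  sk <- mean((tstats - mean(tstats))^3) / sd(tstats)^3
  expect_lt(abs(sk), 3 * sqrt(6 / length(tstats)))
})

test_that("likelihood never decreases and LRT df match parameter counts", {
  s <- simTable(0.3, seed = 55)
  full <- fitChannel(s$tab, "E1", "alpha",
                     modelSpec(c("state", "memory", "state:memory")))
  nested <- fitChannel(s$tab, "E1", "alpha",
                       modelSpec(c("state", "memory")))
  expect_gte(full@logLik, nested@logLik - 1e-8)
  expect_true(all(full@effectTests$chisq >= 0))
  # interaction drop: 1 parameter; memory drop removes its interaction too
  et <- full@effectTests
  expect_equal(et$df[et$term == "state:memory"], 1)
  expect_equal(et$df[et$term == "memory"], 2)
})
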