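test_that("generators are deterministic in the master seed", {
  cfg <- simConfig(seed = 99, nDomesticVarieties = 5, nForeignVarieties = 5,
                   samplesPerVariety = 3)
  v1 <- generateVarieties(cfg); v2 <- generateVarieties(cfg)
  expect_identical(v1, v2)
  expect_identical(generatePopulation(v1, cfg), generatePopulation(v1, cfg))
  expect_false(identical(v1, generateVarieties(simConfig(seed = 100,
    nDomesticVarieties = 5, nForeignVarieties = 5))))
  # sub-streams are independent: population draw does not disturb varieties
  expect_identical(generateVarieties(cfg),
                   { generatePopulation(v1, cfg); generateVarieties(cfg) })
  sim1 <- generateVcf(seed = 42, path = tempfile(fileext = ".vcf"))
  sim2 <- generateVcf(seed = 42, path = tempfile(fileext = ".vcf"))
  expect_identical(readLines(sim1$path), readLines(sim2$path))
})

test_that("fingerprints respect the control and the capacity bound", {
  cfg <- simConfig(seed = 1, nDomesticVarieties = 40, nForeignVarieties = 60,
                   forceSeparable = TRUE)
  v <- generateVarieties(cfg)
  expect_true(all(v$m1 == 1L))
  vals <- judgmentValues(v)
  expect_true(all(vals %% 2 == 1))
  # separable draw: no value shared between origins, none duplicated
  expect_length(intersect(vals[v$origin == "domestic"],
                          vals[v$origin == "foreign"]), 0L)
  expect_false(anyDuplicated(vals) > 0)
  # only 1024 distinct fingerprints exist with the control fixed
  expect_error(generateVarieties(simConfig(nDomesticVarieties = 1024,
                                           nForeignVarieties = 1024,
                                           forceSeparable = TRUE)),
               class = "soyInputError")
})

test_that("noise model flips markers at the configured rates", {
  # zero noise: every grain inherits its variety's judgment value
  cfg0 <- simConfig(seed = 2, nDomesticVarieties = 10,
                    nForeignVarieties = 10, samplesPerVariety = 5,
                    dropoutRate = 0, falseAmpRate = 0)
  v <- generateVarieties(cfg0)
  pop <- generatePopulation(v, cfg0)
  expect_equal(as.integer(judgmentValues(pop)),
               rep(as.integer(judgmentValues(v)), each = 5))
  # total dropout, no false amplification: everything collapses to 1
  cfgD <- simConfig(seed = 2, nDomesticVarieties = 5, nForeignVarieties = 5,
                    samplesPerVariety = 2, dropoutRate = 1, falseAmpRate = 0)
  popD <- generatePopulation(generateVarieties(cfgD), cfgD)
  expect_true(all(judgmentValues(popD) == 1L))
  # dropout only: a grain's value never exceeds its fingerprint's
  cfgS <- simConfig(seed = 3, nDomesticVarieties = 20, nForeignVarieties = 20,
                    samplesPerVariety = 10, dropoutRate = 0.3,
                    falseAmpRate = 0)
  vs <- generateVarieties(cfgS)
  ps <- generatePopulation(vs, cfgS)
  expect_true(all(as.integer(judgmentValues(ps)) <=
                  rep(as.integer(judgmentValues(vs)), each = 10)))
})

test_that("flip counts sit inside binomial 99% bounds at n = 10^4", {
  cfg <- simConfig(seed = 8, nDomesticVarieties = 1, nForeignVarieties = 1,
                   samplesPerVariety = 5000, dropoutRate = 0.1,
                   falseAmpRate = 0.05)
  v <- generateVarieties(cfg)
  pop <- generatePopulation(v, cfg)
  cols <- paste0("m", 2:11)
  fp <- as.matrix(v[rep(1:2, each = 5000), cols])
  ob <- as.matrix(pop[cols])
  nOn <- sum(fp == 1); nOff <- sum(fp == 0)
  drops <- sum(fp == 1 & ob == 0)
  gains <- sum(fp == 0 & ob == 1)
  expect_gte(drops, qbinom(0.005, nOn, 0.1))
  expect_lte(drops, qbinom(0.995, nOn, 0.1))
  expect_gte(gains, qbinom(0.005, nOff, 0.05))
  expect_lte(gains, qbinom(0.995, nOff, 0.05))
})

test_that("lots carry truth labels and mix at the configured fraction", {
  cfg <- simConfig(seed = 4, nDomesticVarieties = 10, nForeignVarieties = 10,
                   lotSize = 24, mixtureFraction = 0.5,
                   dropoutRate = 0, falseAmpRate = 0)
  v <- generateVarieties(cfg)
  lots <- generateLots(v, cfg, nDomesticLots = 2, nForeignLots = 2,
                       nMixedLots = 2)
  expect_equal(nrow(lots), 6 * 24)
  pure <- lots[lots$true_lot_label == "domestic", ]
  expect_true(all(pure$origin == "domestic"))
  pureF <- lots[lots$true_lot_label == "foreign", ]
  expect_true(all(pureF$origin == "foreign"))
  mixed <- lots[lots$true_lot_label == "mixed", ]
  expect_true(any(mixed$origin == "foreign") && any(mixed$origin == "domestic"))
})

test_that("zero-noise separable simulation is classified perfectly", {
  cfg <- simConfig(seed = 6, nDomesticVarieties = 53, nForeignVarieties = 70,
                   samplesPerVariety = 12, dropoutRate = 0, falseAmpRate = 0,
                   forceSeparable = TRUE)
  v <- generateVarieties(cfg)
  pop <- generatePopulation(v, cfg)
  tab <- buildDiscriminationTable(pop)
  expect_length(overlappingValues(tab), 0L)
  expect_equal(performanceSummary(confusionCounts(tab)),
               list(sensitivity = 100.0, selectivity = 100.0,
                    efficiency = 100.0))
})

test_that("marker frequencies fitted from a table are count-weighted", {
  # toy: domestic all at value 3 (markers 1,2), foreign at 1 and 5
  tab <- toyTable(domestic = 3, foreign = c(1, 5),
                  domesticCounts = 4L, foreignCounts = c(1L, 3L))
  f <- fitMarkerFrequencies(tab)
  expect_equal(unname(f["domestic", 1:2]), c(1, 1))
  expect_equal(unname(f["foreign", "m3"]), 0.75)  # 3 of 4 samples carry m3
  expect_equal(unname(f["foreign", "m2"]), 0)
})
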