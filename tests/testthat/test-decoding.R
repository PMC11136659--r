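test_that("the linear decoder matches a nearest-class-mean oracle when separable", {
  # two neurons, widely separated class means, symmetric clouds: the
  # max-margin boundary is the perpendicular bisector, so held-out points
  # classify exactly as nearest class mean
  set.seed(51)
  n <- 40
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- matrix(rnorm(n * 2, sd = 0.3), n, 2)
  x[y == "A", 1] <- x[y == "A", 1] + 3
  tr <- sort(c(sample(which(y == "A"), 15), sample(which(y == "B"), 15)))
  te <- setdiff(seq_len(n), tr)
  fit <- wmdrift:::fitLinearDecoder(x[tr, ], y[tr])
  pred <- wmdrift:::predictDecoder(fit, x[te, ])
  muA <- colMeans(x[tr, ][y[tr] == "A", ]); muB <- colMeans(x[tr, ][y[tr] == "B", ])
  oracle <- ifelse(colSums((t(x[te, ]) - muA)^2) <
                     colSums((t(x[te, ]) - muB)^2), "A", "B")
  expect_equal(as.character(pred), oracle)
})

test_that("train and test splits are disjoint and stratified", {
  set.seed(52)
  y <- factor(rep(c("A", "B", "C"), times = c(20, 12, 8)))
  for (i in 1:20) {
    tr <- wmdrift:::stratifiedSplit(y, 0.9)
    te <- setdiff(seq_along(y), tr)
    expect_length(intersect(tr, te), 0)
    expect_setequal(union(tr, te), seq_along(y))
    # every label present on both sides
    expect_setequal(unique(y[tr]), levels(y))
    expect_setequal(unique(y[te]), levels(y))
  }
})

test_that("a large planted odour effect is decoded nearly perfectly", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 1, nNeurons = 40,
                         trialsPerDay = 60,
                         fracSelective = c(first_odour = 0.5),
                         mixedProb = 0, pairFrac = 0, errorRate = 0,
                         effectRateHi = 2, effectRateLo = 0.1)
  coh <- generateCohort(cfg, seed = 53)
  s <- sessions(coh)[[1]]
  tens <- binActivity(s, cfg$task)
  w <- epochWindows(cfg$task)
  r <- sameDayDecoding(tens, trialTable(s)$firstOdour, w,
                       decodingConfig(nRepeats = 16), epochs = "first_odour",
                       seed = 1)
  expect_gte(epochAccuracy(r, "first_odour"), 0.95)
  # decoding the same labels in the baseline epoch is at chance
  rb <- sameDayDecoding(tens, trialTable(s)$firstOdour, w,
                        decodingConfig(nRepeats = 16), epochs = "baseline",
                        seed = 1)
  expect_lt(abs(epochAccuracy(rb, "baseline") - 0.5), 0.18)
})

test_that("decoding is deterministic under a seed", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 1, nNeurons = 20,
                         trialsPerDay = 40, errorRate = 0)
  coh <- generateCohort(cfg, seed = 54)
  s <- sessions(coh)[[1]]
  tens <- binActivity(s, cfg$task)
  w <- epochWindows(cfg$task)
  r1 <- sameDayDecoding(tens, trialTable(s)$firstOdour, w,
                        decodingConfig(nRepeats = 4), epochs = "first_odour",
                        seed = 9)
  r2 <- sameDayDecoding(tens, trialTable(s)$firstOdour, w,
                        decodingConfig(nRepeats = 4), epochs = "first_odour",
                        seed = 9)
  expect_identical(r1@binAccuracy, r2@binAccuracy)
})

test_that("the top-N curve is consistent and flags sub-single-neuron N", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 1, nNeurons = 30,
                         trialsPerDay = 40,
                         fracSelective = c(first_odour = 0.4),
                         mixedProb = 0, pairFrac = 0, errorRate = 0,
                         effectRateHi = 2, effectRateLo = 0.1)
  coh <- generateCohort(cfg, seed = 55)
  s <- sessions(coh)[[1]]
  tens <- binActivity(s, cfg$task)
  w <- epochWindows(cfg$task)
  gt <- groundTruth(coh)
  ranking <- order(!gt$selective)   # planted selective neurons first
  dc <- decodingConfig(nRepeats = 6, nGrid = c(1, 50, 100))
  curve <- topFractionCurve(tens, trialTable(s)$firstOdour, ranking, w,
                            dc, epoch = "first_odour", seed = 3)
  expect_true(curve$flagged[curve$N == 1])    # 1% of 30 neurons < 1
  expect_equal(curve$nNeurons, c(1, 15, 30))
  # N = 100 equals plain decoding on all neurons with the same seed
  full <- sameDayDecoding(tens, trialTable(s)$firstOdour, w, dc,
                          epochs = "first_odour", seed = 3)
  expect_equal(curve$accuracy[curve$N == 100],
               epochAccuracy(full, "first_odour"), tolerance = 1e-12)
  # a single perfectly informative neuron already decodes well
  expect_gte(curve$accuracy[curve$N == 1], 0.7)
  expect_error(topFractionCurve(tens, trialTable(s)$firstOdour,
                                ranking[-1], w, dc), "permutation")
})

test_that("depth stratification equalizes counts and recovers structure", {
  cfg <- taskConfig()
  w <- epochWindows(cfg)
  set.seed(56)
  nN <- 70
  depths <- runif(nN, 30, 450)
  act <- array(rexp(40 * nN * 150) * 0.1, dim = c(40, nN, 150))
  trials <- makeTrials(rep(c("AC", "AD", "BC", "BD"), 10))
  tens <- binActivity(makeSession(act, trials), cfg)
  res <- depthStratifiedDecoding(tens, depths, trials$firstOdour, w,
                                 decodingConfig(nRepeats = 2),
                                 epoch = "late_delay", seed = 4)
  census <- res$table$census
  expect_equal(res$equalizedCount, min(census))
  expect_true(all(res$table$nUsed == min(census)))
  expect_equal(nrow(res$table), 7)
  expect_equal(res$table$depthHi - res$table$depthLo, rep(60, 7))
  # an interval emptied of neurons is a named error
  expect_error(
    depthStratifiedDecoding(tens, rep(c(100, 400), length.out = nN),
                            trials$firstOdour, w,
                            decodingConfig(nRepeats = 2)),
    "empty depth interval")
})

test_that("four-way category decoding separates a fully separable cohort", {
  # a persistent odour-1 trace plus second-odour cells makes all four
  # categories (AC/AD/BC/BD) separable during the second-odour epoch
  cfg <- generatorConfig(nAnimals = 1, nDays = 1, nNeurons = 40,
                         trialsPerDay = 80,
                         fracSelective = c(first_odour = 0.35,
                                           second_odour = 0.35),
                         mixedProb = 0, pairFrac = 0, carryOverProb = 1,
                         errorRate = 0,
                         effectRateHi = 2.5, effectRateLo = 0.1)
  coh <- generateCohort(cfg, seed = 57)
  s <- sessions(coh)[[1]]
  tens <- binActivity(s, cfg$task)
  w <- epochWindows(cfg$task)
  r <- decodeTrialCategory(tens, trialTable(s)$trialType, w,
                           decodingConfig(nRepeats = 8),
                           epochs = "second_odour", seed = 5)
  expect_gte(epochAccuracy(r, "second_odour"), 0.9)
  # collapsing the four categories to the first odour reproduces binary
  # decoding at least as accurately
  rb <- sameDayDecoding(tens, trialTable(s)$firstOdour, w,
                        decodingConfig(nRepeats = 8),
                        epochs = "second_odour", seed = 5)
  expect_gte(epochAccuracy(rb, "second_odour"),
             epochAccuracy(r, "second_odour") - 0.05)
})
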