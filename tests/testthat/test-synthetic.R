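test_that("planted day-one counts are exact and retention one freezes tuning", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 3, nNeurons = 200,
                         trialsPerDay = 20,
                         fracSelective = c(first_odour = 0.1),
                         mixedProb = 0, pairFrac = 0, retention = 1,
                         crystallizationDay = 4, errorRate = 0)
  coh <- generateCohort(cfg, seed = 3)
  gt <- groundTruth(coh)
  d1 <- gt[gt$day == 1, ]
  expect_equal(sum(d1$selective), 20)           # floor(0.1 * 200)
  expect_true(all(d1$epochs[d1$selective] == "first_odour"))
  # retention 1: identical tuning tables on every day
  for (d in 2:3) {
    dd <- gt[gt$day == d, ]
    expect_identical(dd$epochs, d1$epochs)
    expect_identical(dd$prefOdour1, d1$prefOdour1)
  }
})

test_that("the cohort is a deterministic function of the seed", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 2, nNeurons = 25,
                         trialsPerDay = 15)
  a <- generateCohort(cfg, seed = 42)
  b <- generateCohort(cfg, seed = 42)
  c <- generateCohort(cfg, seed = 43)
  expect_identical(activityTensor(sessions(a)[[1]]),
                   activityTensor(sessions(b)[[1]]))
  expect_identical(groundTruth(a), groundTruth(b))
  expect_false(identical(activityTensor(sessions(a)[[1]]),
                         activityTensor(sessions(c)[[1]])))
  expect_true(all(vapply(sessions(a), function(s)
    all(activityTensor(s) >= 0), logical(1))))
})

test_that("non-selective event mass converges to the configured noise rate", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 1, nNeurons = 150,
                         trialsPerDay = 30, noiseRate = 0.2,
                         fracSelective = c(first_odour = 0), mixedProb = 0,
                         pairFrac = 0, errorRate = 0)
  coh <- generateCohort(cfg, seed = 5)
  tens <- binActivity(sessions(coh)[[1]], cfg$task)
  # 30 trials x 150 neurons x 30 bins = 1.35e5 bin samples
  expect_gt(length(tens@values), 1e5)
  expect_lt(abs(mean(tens@values) - 0.2) / 0.2, 0.05)
})

test_that("day-to-day tuning overlap matches the retention schedule", {
  fs <- c(first_odour = 0.2, late_delay = 0.15, choice = 0.15)
  mp <- 0.3
  # chance that an i.i.d. redraw reproduces (epoch e, preferred label):
  # primary hit, or mixed-extra hit (1 or 2 extras drawn uniformly from the
  # 2 other configured epochs, so P(hit) = E[k]/2 = 0.75), times 1/2 for
  # the label
  pChance <- function(e) {
    S <- sum(fs)
    f <- ifelse(e %in% names(fs), fs[[e]], 0)
    (f + (S - f) * mp * 0.75) * 0.5
  }
  for (rho in c(0, 0.6)) {
    cfg <- generatorConfig(nAnimals = 1, nDays = 2, nNeurons = 2000,
                           trialsPerDay = 12, fracSelective = fs,
                           mixedProb = mp, pairFrac = 0, retention = rho,
                           crystallizationDay = 3, errorRate = 0,
                           effectRateHi = 0.2, effectRateLo = 0.2)
    coh <- generateCohort(cfg, seed = 11 + round(10 * rho))
    ov <- groundTruthSummary(coh)$overlap
    for (e in names(fs)) {
      expected <- rho + (1 - rho) * pChance(e)
      got <- ov$overlap[ov$epoch == e]
      nTuned <- sum(cfg$fracSelective[[e]] * 2000)  # approximate census
      band <- 1.96 * sqrt(expected * (1 - expected) / nTuned) + 0.02
      expect_lt(abs(got - expected), band + 0.03)
    }
  }
})

test_that("simulated behaviour has the planted error rate and abort rule", {
  withr::with_seed(31, {
    tr <- simulateBehaviour(500, errorRate = 0)
    expect_equal(nrow(tr), 500)
    expect_equal(behaviourSummary(tr)$performance, 1)

    big <- simulateBehaviour(5000, errorRate = 0.2, applyAbort = FALSE)
    p <- behaviourSummary(big)$performance
    expect_lt(abs(p - 0.8), 1.96 * sqrt(0.8 * 0.2 / 5000) + 0.005)

    # with errors and the abort rule on, sessions can only shrink
    tr2 <- simulateBehaviour(200, errorRate = 0.3, applyAbort = TRUE)
    expect_lte(nrow(tr2), 200)
    expect_equal(applyAbortRule(tr2$outcome), nrow(tr2))
  })
})

test_that("error trials degrade only the late-delay effect", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 1, nNeurons = 2,
                         trialsPerDay = 400,
                         fracSelective = c(late_delay = 0.5),
                         mixedProb = 0, pairFrac = 0, errorRate = 0.3,
                         errorDegrade = 1, applyAbort = FALSE,
                         effectRateHi = 3, effectRateLo = 0.3,
                         noiseRate = 0.3)
  coh <- generateCohort(cfg, seed = 8)
  s <- sessions(coh)[[1]]
  gt <- groundTruth(coh)
  j <- which(gt$selective)[1]
  tr <- trialTable(s)
  tens <- binActivity(s, cfg$task)
  m <- epochMean(tens, epochWindows(cfg$task), "late_delay")[, j]
  pref <- tr$firstOdour == gt$prefOdour1[j]
  # preferred-correct trials carry the effect; preferred-error trials do not
  expect_gt(mean(m[pref & !tr$isError]), 2)
  expect_lt(mean(m[pref & tr$isError]), 0.8)
})
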