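test_that("rank-sum p-values equal exhaustive permutation enumeration", {
  # canonical small case: {1,2,3} vs {4,5,6} has exact two-sided p = 0.1
  tens <- tensorFromTrialValues(c(1, 2, 3, 4, 5, 6))
  res <- selectivityTest(tens, epochWindows(taskConfig()), "first_odour",
                         c("A", "A", "A", "B", "B", "B"))
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$preferred, "B")
  expect_false(res$selective)
  expect_equal(exactRankSumP(c(1, 2, 3), c(4, 5, 6)), 0.1)

  # random continuous 4 vs 4 samples against the brute-force oracle
  set.seed(41)
  w <- epochWindows(taskConfig())
  for (i in 1:10) {
    v <- round(runif(8), 3)
    labs <- rep(c("A", "B"), each = 4)
    res <- selectivityTest(tensorFromTrialValues(v), w, "first_odour", labs)
    expect_equal(res$p, exactRankSumP(v[1:4], v[5:8]), tolerance = 1e-12)
  }
})

test_that("degenerate and invalid label inputs are handled", {
  w <- epochWindows(taskConfig())
  tens <- tensorFromTrialValues(rep(2, 8))
  res <- selectivityTest(tens, w, "first_odour", rep(c("A", "B"), 4))
  expect_equal(res$p, 1)
  expect_false(res$selective)
  expect_true(res$ambiguous)
  expect_error(selectivityTest(tens, w, "first_odour", rep("A", 8)),
               "single group")
  expect_error(selectivityTest(tens, w, "first_odour",
                               c("A", "A", "B", rep("B", 5))),
               "at least 3 trials")
})

test_that("pure/mixed classification follows the selective-entry count", {
  res <- data.frame(
    neuronId = c("a", "a", "a", "b", "b", "c"),
    epoch = c("first_odour", "early_delay", "choice",
              "first_odour", "choice", "late_delay"),
    comparison = "x", selective = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  prof <- classifyProfile(res)
  expect_equal(prof$category[prof$neuronId == "a"], "pure")
  expect_equal(prof$category[prof$neuronId == "b"], "mixed")
  expect_equal(prof$category[prof$neuronId == "c"], "none")
})

test_that("associated-pair cells require the rewarded odour pairings", {
  mk <- function(id, epoch, cmp, pref, sel = TRUE)
    data.frame(neuronId = id, epoch = epoch, comparison = cmp,
               preferred = pref, selective = sel)
  res <- rbind(
    mk("ac", "first_odour", "first_odour", "A"),
    mk("ac", "second_odour", "second_odour", "C"),
    mk("bd", "first_odour", "first_odour", "B"),
    mk("bd", "second_odour", "second_odour", "D"),
    mk("ad", "first_odour", "first_odour", "A"),   # wrong pairing
    mk("ad", "second_odour", "second_odour", "D"),
    mk("a_", "first_odour", "first_odour", "A"))   # no second-odour partner
  expect_equal(associatedPairCells(res), c("ac", "bd"))
  expect_equal(associatedPairCells(res[res$neuronId == "a_", ]), character(0))
})

test_that("planted associated-pair cells are recovered", {
  cfg <- generatorConfig(nAnimals = 1, nDays = 1, nNeurons = 200,
                         trialsPerDay = 120,
                         fracSelective = c(first_odour = 0.1),
                         mixedProb = 0, pairFrac = 0.05, errorRate = 0,
                         effectRateHi = 1.5, effectRateLo = 0.2)
  coh <- generateCohort(cfg, seed = 17)
  s <- sessions(coh)[[1]]
  g <- selectivityGrid(s, cfg$task, epochWindows(cfg$task))
  found <- associatedPairCells(g)
  planted <- groundTruth(coh)$neuronId[groundTruth(coh)$pairCell]
  expect_equal(length(planted), 10)
  # recovery within a binomial band around the planted count at high power
  expect_gte(length(intersect(found, planted)), 8)
  # few spurious pair cells among the unplanted
  expect_lte(length(setdiff(found, planted)), 3)
})

test_that("the FFT circular-shift statistic matches a brute-force loop", {
  set.seed(43)
  X <- matrix(rexp(60 * 3), 60, 3)
  I <- c(4:7, 24:27, 44:47)
  S <- wmdrift:::circularEpochMeans(X, I)
  L <- nrow(X)
  for (s in c(0, 1, 5, 33, 59)) {
    manual <- colMeans(X[((I - 1 + s) %% L) + 1, , drop = FALSE])
    expect_equal(S[s + 1, ], manual, tolerance = 1e-10)
  }
})

test_that("activity-field p has the permutation floor and degenerate cases", {
  cfg <- taskConfig()
  w <- epochWindows(cfg)
  # all-zero neuron is never significant
  act <- array(0, dim = c(3, 1, 150))
  r0 <- activityFieldTest(makeSession(act), cfg, w, "late_delay",
                          nShuffles = 100, seed = 1)
  expect_equal(r0$p, 1)
  expect_false(r0$significant)

  # single trial with event mass filling the whole epoch: every nonzero
  # shift moves mass out, so p sits at the permutation floor 1/(n+1)
  act1 <- array(0, dim = c(1, 1, 150))
  frames <- which(wmdrift:::frameStarts(cfg) >= 4 &
                    wmdrift:::frameStarts(cfg) < 6)
  act1[1, 1, frames] <- 1
  r1 <- activityFieldTest(makeSession(act1), cfg, w, "late_delay",
                          nShuffles = 1000, seed = 2)
  expect_equal(r1$p, 1 / 1001, tolerance = 1e-12)
  expect_true(r1$significant)

  # multi-trial epoch-locked mass: only trial-period realignments can tie,
  # so p stays near the floor
  act3 <- array(0, dim = c(8, 1, 150))
  act3[, 1, frames] <- rexp(8 * length(frames))
  r3 <- activityFieldTest(makeSession(act3), cfg, w, "late_delay",
                          nShuffles = 1000, seed = 3)
  expect_lt(r3$p, 0.05)
})

test_that("movement correlation flags identical traces and not constants", {
  set.seed(44)
  x <- abs(rnorm(400))
  r <- movementCorrelationTest(x, x, nShuffles = 300, seed = 1)
  expect_equal(r$r, 1)
  expect_true(r$significant)

  rc <- movementCorrelationTest(rep(1, 400), x, nShuffles = 50, seed = 1)
  expect_true(rc$degenerate)
  expect_false(rc$significant)
  expect_error(movementCorrelationTest(x[1:5], x[1:5]), "at least 10")
  expect_error(movementCorrelationTest(x, x[1:100]), "equal length")
})

test_that("movement-correlation false-flag rate respects the 2-s.d. rule", {
  # independent white-noise traces: under the Gaussian approximation the
  # two-sided 2-s.d. rule flags about 4.6%, bounded by 7%
  set.seed(45)
  flags <- vapply(1:500, function(i) {
    movementCorrelationTest(rnorm(120), rnorm(120), nShuffles = 119)$significant
  }, logical(1))
  expect_lte(mean(flags), 0.07 + 0.02)
})

test_that("sequence correlation separates planted trial-type sequences", {
  cfg <- taskConfig()
  w <- epochWindows(cfg)
  set.seed(46)
  # identical coding across types: per-neuron r = 1
  profile <- matrix(rexp(20 * 30) + 0.01, 20, 30)   # neurons x bins
  base <- array(0, dim = c(8, 20, 30))
  for (t in 1:8) base[t, , ] <- profile
  types <- rep(c("AC", "BD"), each = 4)
  tensSame <- new("TrialTensor", values = base,
                  binStarts = seq(-5, 9.5, by = 0.5), binWidth = 0.5,
                  sessionId = "t")
  sc <- sequenceCorrelation(tensSame, types)
  expect_true(all(abs(sc$perNeuron$r - 1) < 1e-9))

  # type-specific delay sequences: cross-type correlation is minimal
  # within the delay window
  act <- array(rexp(12 * 24 * 150) * 0.05, dim = c(12, 24, 150))
  types2 <- rep(c("AC", "BD"), each = 6)
  delayFrames <- 61:110   # 1..6 s after onset
  for (j in 1:24) {
    peakA <- delayFrames[1 + ((j * 2) %% 50)]
    peakB <- delayFrames[1 + ((j * 2 + 25) %% 50)]
    act[types2 == "AC", j, peakA + (-2:2)] <- 3
    act[types2 == "BD", j, peakB + (-2:2)] <- 3
  }
  tens <- binActivity(makeSession(act, makeTrials(types2)), cfg)
  sc2 <- sequenceCorrelation(tens, types2)
  delayBins <- which(tens@binStarts >= 1 & tens@binStarts < 6)
  outBins <- which(tens@binStarts < 0)
  expect_lt(mean(sc2$perBin$r[delayBins], na.rm = TRUE),
            mean(sc2$perBin$r[outBins], na.rm = TRUE) + 0.2)
  expect_lt(min(sc2$perBin$r[delayBins], na.rm = TRUE), 0.2)

  # per-neuron correlations are invariant to neuron order
  perm <- sample(24)
  tensP <- tens; tensP@values <- tens@values[, perm, ]
  scP <- sequenceCorrelation(tensP, types2)
  expect_equal(scP$perNeuron$r, sc2$perNeuron$r[perm], tolerance = 1e-12)
})
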