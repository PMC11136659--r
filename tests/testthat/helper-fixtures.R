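# Small in-code fixtures shared across test files.

# Trial table with balanced first odours; licked follows reward (no errors)
# unless stated otherwise.
makeTrials <- function(types) {
  first <- substr(types, 1, 1)
  second <- substr(types, 2, 2)
  rewarded <- types %in% c("AC", "BD")
  data.frame(trialType = types, firstOdour = first, secondOdour = second,
             rewarded = rewarded, licked = rewarded,
             outcome = ifelse(rewarded, "hit", "correct_rejection"),
             isError = FALSE, stringsAsFactors = FALSE)
}

# Session wrapper around an explicit activity array.
makeSession <- function(activity, trials = NULL, frameRate = 10,
                        animal = "t01", day = 1L) {
  nT <- dim(activity)[1]; nN <- dim(activity)[2]
  if (is.null(trials))
    trials <- makeTrials(rep(c("AC", "AD", "BC", "BD"), length.out = nT))
  newSession(animal, day, trials, activity,
             sprintf("n%03d", seq_len(nN)),
             data.frame(x = seq_len(nN) * 30, y = rep(0, nN),
                        depth = rep(100, nN)),
             frameRate = frameRate)
}

# Exhaustive two-sided rank-sum permutation p-value: enumerates every
# assignment of the pooled values to groups of size n1/n2 and applies the
# standard two-sided doubling convention to the Mann-Whitney U statistic.
exactRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, uOf)
  uObs <- uOf(seq_len(n1))
  mid <- n1 * n2 / 2
  if (uObs > mid) p <- 2 * mean(us >= uObs)
  else if (uObs < mid) p <- 2 * mean(us <= uObs)
  else p <- 1
  min(p, 1)
}

# Tensor whose per-trial epoch means equal `values` in every bin (one
# neuron), for driving selectivityTest with chosen numbers.
tensorFromTrialValues <- function(values, config = taskConfig()) {
  nT <- length(values)
  act <- array(0, dim = c(nT, 1, framesPerTrial(config)))
  for (t in seq_len(nT)) act[t, 1, ] <- values[t] / (config@frameRate *
                                                       config@binWidth)
  binActivity(makeSession(act), config)
}

wrapMatrix <- function(acc, animal = "sim") {
  nD <- nrow(acc)
  new("CrossDayMatrix", acc = acc,
      nMatched = matrix(100L, nD, nD), days = seq_len(nD),
      epoch = "first_odour", labelSet = "first_odour", animalId = animal)
}
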