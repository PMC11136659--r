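## Cross-day decoder generalization, early/late block statistics,
## day-shuffle permutation tests, and crystallization-day estimation.

#' Cross-day decoder generalization matrix for one animal
#'
#' Off-diagonal entries train a per-bin linear decoder on all trials of day i
#' (restricted to the neurons matched between days i and j) and test it on
#' all trials of day j; the diagonal holds the same-day cross-validated
#' accuracy so the matrix is comparable on and off the diagonal. Neuron scope
#' is the pairwise intersection per (i, j) pair, which maximizes the neurons
#' available to each pair.
#'
#' @param cohort a [Cohort-class].
#' @param animal animal identifier.
#' @param labelSet \code{"first_odour"}, \code{"choice"} or
#'   \code{"category"}.
#' @param taskCfg a [TaskConfig-class].
#' @param windows an [EpochWindows-class].
#' @param epoch epoch decoded.
#' @param config a \code{DecodingConfig} (its repeats apply to the
#'   diagonal).
#' @param matching optional precomputed [matchAcrossDays] list; by default
#'   matching is recomputed from centroids at \code{maxDist}.
#' @param maxDist centroid-matching ceiling (micrometres).
#' @param minMatched minimum matched neurons required per pair; entries
#'   below it are NA.
#' @param seed integer master seed.
#' @return A [CrossDayMatrix-class].
#' @export
crossDayDecoding <- function(cohort, animal, labelSet = "first_odour",
                             taskCfg = taskConfig(),
                             windows = epochWindows(taskCfg),
                             epoch = "first_odour",
                             config = decodingConfig(nRepeats = 8),
                             matching = NULL, maxDist = 10,
                             minMatched = 10, seed = NULL) {
  ss <- animalSessions(cohort, animal)
  days <- vapply(ss, dayIndex, integer(1))
  nD <- length(ss)
  if (is.null(matching)) matching <- matchAcrossDays(cohort, animal, maxDist)
  tensors <- lapply(ss, binActivity, config = taskCfg)
  labOf <- function(s) {
    tr <- trialTable(s)
    switch(labelSet,
           first_odour = tr$firstOdour,
           choice = ifelse(tr$licked, "lick", "nolick"),
           category = tr$trialType,
           stop(sprintf("unknown labelSet '%s'", labelSet)))
  }
  acc <- matrix(NA_real_, nD, nD, dimnames = list(days, days))
  nm <- matrix(NA_integer_, nD, nD, dimnames = list(days, days))
  for (a in seq_len(nD)) {
    r <- sameDayDecoding(tensors[[a]], labOf(ss[[a]]), windows, config,
                         epochs = epoch,
                         seed = if (is.null(seed)) NULL
                                else childSeed(seed, a))
    acc[a, a] <- epochAccuracy(r, epoch)
    nm[a, a] <- nNeurons(ss[[a]])
  }
  bins <- selectBins(tensors[[1]], windows, epoch)
  for (a in seq_len(nD)) for (b in seq_len(nD)) {
    if (a == b) next
    key <- sprintf("%d-%d", min(days[a], days[b]), max(days[a], days[b]))
    mt <- matching[[key]]
    if (a < b) { idA <- mt$idI; idB <- mt$idJ } else { idA <- mt$idJ; idB <- mt$idI }
    nm[a, b] <- length(idA)
    if (length(idA) < minMatched) next
    ia <- match(idA, neuronIds(ss[[a]]))
    ib <- match(idB, neuronIds(ss[[b]]))
    ya <- factor(labOf(ss[[a]])); yb <- factor(labOf(ss[[b]]), levels = levels(ya))
    perBin <- vapply(bins, function(bn) {
      xa <- tensors[[a]]@values[, ia, bn, drop = FALSE]; dim(xa) <- dim(xa)[1:2]
      xb <- tensors[[b]]@values[, ib, bn, drop = FALSE]; dim(xb) <- dim(xb)[1:2]
      fit <- fitLinearDecoder(xa, ya, config$cost)
      mean(predictDecoder(fit, xb) == yb)
    }, numeric(1))
    acc[a, b] <- mean(perBin)
  }
  new("CrossDayMatrix", acc = acc, nMatched = nm, days = days,
      epoch = epoch, labelSet = labelSet, animalId = animal)
}

#' Early/late block stability statistics across animals
#'
#' Per animal, averages the off-diagonal generalization accuracy among the
#' early-block day pairs and among the late-block day pairs (train and test
#' day both inside the block, train != test); across animals, tests whether
#' the late-block mean exceeds the early-block mean with a one-sided
#' unpaired two-sample t-test (the stabilization hypothesis is
#' directional).
#'
#' @param matrices list of [CrossDayMatrix-class], one per animal.
#' @param earlyDays,lateDays day-index vectors defining the two disjoint
#'   blocks (e.g. 1:3 vs 5:7, or 1:5 vs 6:10).
#' @return list with per-animal block means, the mean difference, t
#'   statistic and one-sided p.
#' @export
blockStabilityStat <- function(matrices, earlyDays, lateDays) {
  if (length(intersect(earlyDays, lateDays)))
    stop("early and late blocks must be disjoint")
  if (length(earlyDays) < 2 || length(lateDays) < 2)
    stop("each block needs at least 2 days (no off-diagonal pairs otherwise)")
  early <- vapply(matrices, function(m)
    offDiagMean(m@acc, earlyDays, m@days), numeric(1))
  late <- vapply(matrices, function(m)
    offDiagMean(m@acc, lateDays, m@days), numeric(1))
  diffMean <- mean(late) - mean(early)
  tt <- if (length(matrices) >= 2 && stats::sd(c(late, early)) > 0)
    stats::t.test(late, early, alternative = "greater", var.equal = FALSE)
  else list(statistic = if (diffMean == 0) 0 else NA_real_,
            p.value = if (diffMean == 0) 1 else NA_real_)
  list(earlyMeans = early, lateMeans = late, difference = diffMean,
       t = unname(tt$statistic), p = tt$p.value,
       earlyDays = earlyDays, lateDays = lateDays)
}

#' Day-identity permutation test of block stability
#'
#' Permutes the day identities (rows and columns jointly, the same
#' permutation applied to every animal's matrix), recomputes the late-minus-
#' early block difference averaged across animals, and reports the one-sided
#' Monte Carlo p-value \code{(1 + #\{perm >= observed\}) / (nPerm + 1)}.
#'
#' @inheritParams blockStabilityStat
#' @param nPerm number of sampled day permutations.
#' @param seed integer seed.
#' @return list with \code{observed} difference, \code{p}, and the permuted
#'   differences.
#' @export
dayShuffleTest <- function(matrices, earlyDays, lateDays, nPerm = 1000,
                           seed = NULL) {
  days <- matrices[[1]]@days
  blockDiff <- function(perm) {
    mean(vapply(matrices, function(m) {
      acc <- m@acc[perm, perm]
      offDiagMean(acc, lateDays, days) - offDiagMean(acc, earlyDays, days)
    }, numeric(1)))
  }
  obs <- blockDiff(seq_along(days))
  perms <- withSeed(seed, replicate(nPerm, sample(seq_along(days))))
  null <- apply(perms, 2, blockDiff)
  list(observed = obs, p = (1 + sum(null >= obs)) / (nPerm + 1),
       null = null, nPerm = nPerm)
}

#' Estimate the crystallization (stabilization) day
#'
#' Scans candidate change points c and scores each by the mean off-diagonal
#' generalization accuracy among day pairs at or after c minus the mean
#' among pairs before c (both sides need at least one off-diagonal pair, so
#' candidates run from day 3 to the second-to-last day). The estimate is the
#' arg-max; if the best contrast is below \code{margin} no change point is
#' declared. An optional bootstrap over off-diagonal cells gives a
#' confidence band for the contrast profile.
#'
#' @param matrix a [CrossDayMatrix-class], or a plain day x day accuracy
#'   matrix (e.g. averaged across animals).
#' @param margin minimum contrast required to declare a change point.
#' @param nBoot bootstrap resamples of the off-diagonal cells (0 = none).
#' @param seed integer seed for the bootstrap.
#' @return list with \code{day} (estimated crystallization day or NA),
#'   \code{profile} data.frame (candidate, contrast), and bootstrap
#'   quantiles when requested.
#' @export
estimateCrystallizationDay <- function(matrix, margin = 0.1, nBoot = 0,
                                       seed = NULL) {
  if (is(matrix, "CrossDayMatrix")) { acc <- matrix@acc; days <- matrix@days }
  else { acc <- matrix; days <- seq_len(nrow(matrix)) }
  nD <- length(days)
  if (nD < 4) stop("need at least 4 days to estimate a change point")
  contrastAt <- function(acc, c) {
    offDiagMean(acc, days[days >= c], days) -
      offDiagMean(acc, days[days < c], days)
  }
  cand <- days[days >= days[3] & days <= days[nD - 1]]
  prof <- vapply(cand, function(c) contrastAt(acc, c), numeric(1))
  best <- which.max(prof)
  day <- if (prof[best] >= margin) cand[best] else NA_integer_
  out <- list(day = day,
              profile = data.frame(candidate = cand, contrast = prof))
  if (nBoot > 0) {
    off <- which(row(acc) != col(acc) & !is.na(acc))
    boot <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      acc2 <- acc
      acc2[off] <- acc[sample(off, length(off), replace = TRUE)]
      cand[which.max(vapply(cand, function(c) contrastAt(acc2, c),
                            numeric(1)))]
    }, numeric(1)))
    out$bootQuantiles <- stats::quantile(boot, c(0.025, 0.5, 0.975))
  }
  out
}

#' Regression of generalization accuracy on day gap
#'
#' Fits \code{accuracy ~ |train day - test day|} over the off-diagonal
#' entries; under a frozen (fully retained) code the expected slope is zero,
#' while drift makes it negative.
#'
#' @param matrix a [CrossDayMatrix-class] or plain matrix.
#' @return list with \code{slope}, 95\% \code{ci} and the fitted lm.
#' @export
dayGapSlope <- function(matrix) {
  acc <- if (is(matrix, "CrossDayMatrix")) matrix@acc else matrix
  ij <- which(row(acc) != col(acc) & !is.na(acc), arr.ind = TRUE)
  df <- data.frame(gap = abs(ij[, 1] - ij[, 2]), acc = acc[ij])
  fit <- stats::lm(acc ~ gap, data = df)
  ci <- stats::confint(fit)["gap", ]
  list(slope = unname(stats::coef(fit)["gap"]), ci = unname(ci), fit = fit)
}
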