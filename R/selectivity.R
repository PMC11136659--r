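## Neuron-level statistics: circular-shuffle activity fields, rank-sum
## odour/choice selectivity, pure/mixed taxonomy, associated-pair cells,
## movement correlation and AC/BD sequence correlation.

## Circular cross-correlation of each column of X with an index set:
## out[s + 1, j] = mean over i in I of X[((i - 1 + s) %% L) + 1, j],
## computed for every shift s = 0..L-1 at once via the FFT.
circularEpochMeans <- function(X, I) {
  L <- nrow(X)
  ind <- numeric(L); ind[I] <- 1
  G <- Conj(stats::fft(ind))
  F <- stats::mvfft(X)
  S <- Re(stats::mvfft(F * G, inverse = TRUE)) / L / length(I)
  S
}

#' Significant-activity-field test by circular shuffling
#'
#' For each neuron, the across-trial mean activity within an epoch is
#' compared with a null built by circularly shifting the whole-session
#' concatenated trace (trials back to back) by a uniform random offset per
#' shuffle and recomputing the same statistic. Shifting the entire session
#' trace preserves the trace's autocorrelation, which per-trial independent
#' shifts would destroy. The test is one-sided (activation):
#' \code{p = (1 + #\{null >= observed\}) / (nShuffles + 1)}.
#'
#' @param session a [Session-class].
#' @param config a [TaskConfig-class].
#' @param windows an [EpochWindows-class].
#' @param epoch epoch name.
#' @param nShuffles number of circular shuffles (default 1000).
#' @param alphaField significance level (default 0.05).
#' @param seed integer seed for the shuffle offsets.
#' @return data.frame with one row per neuron: neuronId, epoch, observed,
#'   nullMean, nullSd, p, significant, nShuffles.
#' @export
activityFieldTest <- function(session, config, windows, epoch,
                              nShuffles = 1000, alphaField = 0.05,
                              seed = NULL) {
  if (nTrials(session) < 1) stop("session has no trials")
  act <- activityTensor(session)
  d <- dim(act)
  nF <- d[3]
  ts <- frameStarts(config)[seq_len(nF)]
  win <- epochWindow(windows, epoch)
  epFrames <- which(ts >= win[1] - 1e-9 & ts < win[2] - 1e-9)
  if (!length(epFrames)) stop(sprintf("epoch '%s' covers no frames", epoch))
  L <- d[1] * nF
  ## concatenate trials: index of (trial t, frame f) is (t-1)*nF + f
  I <- as.vector(outer(epFrames, (seq_len(d[1]) - 1) * nF, "+"))
  X <- matrix(aperm(act, c(3, 1, 2)), nrow = L)  # frame-within-trial major
  S <- circularEpochMeans(X, I)
  obs <- S[1, ]
  offsets <- withSeed(seed, sample.int(L - 1, nShuffles, replace = TRUE))
  null <- S[offsets + 1, , drop = FALSE]
  p <- (1 + colSums(null >= rep(obs, each = nShuffles))) / (nShuffles + 1)
  allZero <- colSums(X) == 0
  p[allZero] <- 1
  data.frame(neuronId = neuronIds(session), epoch = epoch, observed = obs,
             nullMean = colMeans(null), nullSd = apply(null, 2, stats::sd),
             p = p, significant = p < alphaField & !allZero,
             nShuffles = nShuffles, stringsAsFactors = FALSE)
}

#' Rank-sum selectivity test per neuron
#'
#' Compares the per-trial mean epoch activity between two trial groups
#' (odour A vs B, odour C vs D, or lick vs no-lick) with the two-sided
#' Wilcoxon rank-sum test; a neuron is selective at \code{p < alpha}
#' (default 0.01, i.e. a 99\% confidence level). The exact null distribution
#' is used for small untied samples (min group size <= 10); otherwise the
#' normal approximation with tie and continuity correction. The effect size
#' is the rank-based AUC (probability that a random group-1 trial exceeds a
#' random group-2 trial); the preferred label is the group with the larger
#' mean, ties broken toward the first label and flagged ambiguous.
#'
#' @param tensor a [TrialTensor-class].
#' @param windows an [EpochWindows-class].
#' @param epoch epoch over which trial means are taken.
#' @param labels per-trial labels (exactly two distinct values).
#' @param comparison comparison name recorded in the output.
#' @param alpha significance level.
#' @param ids neuron identifiers (defaults to column index).
#' @return data.frame with one row per neuron: neuronId, epoch, comparison,
#'   p, auc, preferred, ambiguous, selective.
#' @export
selectivityTest <- function(tensor, windows, epoch, labels,
                            comparison = "first_odour A-vs-B", alpha = 0.01,
                            ids = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) < 2) stop("labels contain a single group")
  if (length(lv) > 2) stop("labels must contain exactly two groups")
  if (min(table(labels)) < 3) stop("need at least 3 trials per label")
  m <- epochMean(tensor, windows, epoch)
  if (is.null(ids)) ids <- sprintf("n%04d", seq_len(ncol(m)))
  g1 <- labels == lv[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[g1, j]; y <- m[!g1, j]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
      p <- 1; U <- n1 * n2 / 2
    } else {
      wt <- suppressWarnings(stats::wilcox.test(
        x, y, exact = min(n1, n2) <= 10, correct = TRUE))
      p <- wt$p.value
      U <- unname(wt$statistic)
    }
    mx <- mean(x); my <- mean(y)
    amb <- isTRUE(all.equal(mx, my))
    pref <- if (amb) lv[1] else if (mx > my) lv[1] else lv[2]
    data.frame(neuronId = ids[j], epoch = epoch, comparison = comparison,
               p = p, auc = U / (n1 * n2), preferred = pref,
               ambiguous = amb, selective = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full selectivity grid for one session
#'
#' Runs [selectivityTest] for the standard comparisons: first-odour identity
#' during the first-odour, early-delay and late-delay epochs, second-odour
#' identity during the second-odour epoch, and choice (lick vs no-lick)
#' during the choice epoch.
#'
#' @param session a [Session-class].
#' @param config a [TaskConfig-class].
#' @param windows an [EpochWindows-class].
#' @param alpha significance level.
#' @return combined data.frame of [selectivityTest] results.
#' @export
selectivityGrid <- function(session, config, windows, alpha = 0.01) {
  tensor <- binActivity(session, config)
  tr <- trialTable(session)
  ids <- neuronIds(session)
  grid <- list(
    list(epoch = "first_odour", labels = tr$firstOdour, cmp = "first_odour"),
    list(epoch = "early_delay", labels = tr$firstOdour, cmp = "first_odour"),
    list(epoch = "late_delay", labels = tr$firstOdour, cmp = "first_odour"),
    list(epoch = "second_odour", labels = tr$secondOdour, cmp = "second_odour"),
    list(epoch = "choice", labels = ifelse(tr$licked, "lick", "nolick"),
         cmp = "choice"))
  out <- lapply(grid, function(g) {
    selectivityTest(tensor, windows, g$epoch, g$labels, comparison = g$cmp,
                    alpha = alpha, ids = ids)
  })
  do.call(rbind, out)
}

#' Classify neurons as purely or mixed selective
#'
#' A neuron is purely selective if it is selective for exactly one
#' (epoch, comparison) entry and shows no selectivity for any other parameter
#' at any other time; mixed if selective for two or more entries; otherwise
#' unselective.
#'
#' @param results a selectivity grid (from [selectivityGrid] or row-bound
#'   [selectivityTest] outputs) covering the complete grid per neuron.
#' @return data.frame with neuronId, nSelective, category
#'   ("pure"/"mixed"/"none").
#' @export
classifyProfile <- function(results) {
  counts <- tapply(results$selective, results$neuronId, sum)
  data.frame(neuronId = names(counts), nSelective = as.integer(counts),
             category = ifelse(counts == 0, "none",
                               ifelse(counts == 1, "pure", "mixed")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Neurons selective for associated pairs of rewarded odours
#'
#' Returns the neurons selective for odour A during the first-odour epoch and
#' odour C during the second-odour epoch, or for odour B and odour D — the
#' rewarded odour pairings.
#'
#' @param results a selectivity grid containing first_odour and second_odour
#'   comparisons.
#' @return character vector of neuron ids.
#' @export
associatedPairCells <- function(results) {
  o1 <- results[results$comparison == "first_odour" &
                  results$epoch == "first_odour" & results$selective, ]
  o2 <- results[results$comparison == "second_odour" & results$selective, ]
  ac <- intersect(o1$neuronId[o1$preferred == "A"],
                  o2$neuronId[o2$preferred == "C"])
  bd <- intersect(o1$neuronId[o1$preferred == "B"],
                  o2$neuronId[o2$preferred == "D"])
  sort(union(ac, bd))
}

#' Movement-correlation test with a circular-shuffle null
#'
#' Pearson correlation between a neuron's activity trace and the locomotion
#' trace, against a null of 1000 circularly shuffled locomotion traces; the
#' neuron is significantly movement-correlated if its coefficient lies at
#' least two null standard deviations from the null mean.
#'
#' @param trace neuron activity trace (per frame).
#' @param locomotion locomotion trace, same length.
#' @param nShuffles number of circular shuffles.
#' @param seed integer seed.
#' @return list with r, nullMean, nullSd, significant, degenerate.
#' @export
movementCorrelationTest <- function(trace, locomotion, nShuffles = 1000,
                                    seed = NULL) {
  L <- length(trace)
  if (length(locomotion) != L) stop("traces must have equal length")
  if (L < 10) stop("traces must have at least 10 frames")
  sx <- stats::sd(trace); sy <- stats::sd(locomotion)
  if (sx == 0 || sy == 0)
    return(list(r = NA_real_, nullMean = NA_real_, nullSd = NA_real_,
                significant = FALSE, degenerate = TRUE))
  ## cross-products at all circular lags via the FFT, then Pearson r
  cp <- Re(stats::fft(stats::fft(trace) * Conj(stats::fft(locomotion)),
                      inverse = TRUE)) / L
  rAll <- (cp - L * mean(trace) * mean(locomotion)) / ((L - 1) * sx * sy)
  rObs <- rAll[1]
  offsets <- withSeed(seed, sample.int(L - 1, nShuffles, replace = TRUE))
  null <- rAll[offsets + 1]
  list(r = rObs, nullMean = mean(null), nullSd = stats::sd(null),
       significant = abs(rObs - mean(null)) >= 2 * stats::sd(null),
       degenerate = FALSE)
}

#' Cross-trial-type sequence correlation (AC vs BD trials)
#'
#' Averages each neuron's binned trace over AC and over BD trials, reports
#' the per-neuron Pearson correlation between the two mean traces, each
#' neuron's peak time under either trial type, and the per-timebin
#' correlation of the two population patterns across neurons (the profile
#' whose minimum locates where the delay-period sequences diverge).
#'
#' @param tensor a [TrialTensor-class].
#' @param trialTypes per-trial type labels (AC/AD/BC/BD).
#' @param typeA,typeB the two (rewarded) trial types compared.
#' @return list with data.frame \code{perNeuron} (neuronId, r, peakBinA,
#'   peakBinB) and data.frame \code{perBin} (bin, binStart, r).
#' @export
sequenceCorrelation <- function(tensor, trialTypes, typeA = "AC",
                                typeB = "BD") {
  iA <- trialTypes == typeA; iB <- trialTypes == typeB
  if (sum(iA) < 3 || sum(iB) < 3)
    stop("need at least 3 trials of each type")
  v <- tensor@values
  mA <- apply(v[iA, , , drop = FALSE], c(2, 3), mean)  # neurons x bins
  mB <- apply(v[iB, , , drop = FALSE], c(2, 3), mean)
  rNeuron <- vapply(seq_len(nrow(mA)), function(j) {
    if (stats::sd(mA[j, ]) == 0 || stats::sd(mB[j, ]) == 0) NA_real_
    else stats::cor(mA[j, ], mB[j, ])
  }, numeric(1))
  rBin <- vapply(seq_len(ncol(mA)), function(b) {
    if (stats::sd(mA[, b]) == 0 || stats::sd(mB[, b]) == 0) NA_real_
    else stats::cor(mA[, b], mB[, b])
  }, numeric(1))
  list(
    perNeuron = data.frame(
      neuron = seq_len(nrow(mA)), r = rNeuron,
      peakBinA = apply(mA, 1, which.max), peakBinB = apply(mB, 1, which.max)),
    perBin = data.frame(bin = seq_len(ncol(mA)),
                        binStart = tensor@binStarts, r = rBin))
}
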