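## Task timeline, epoch windows, binning and response-map normalization.

#' Build named epoch windows from a task configuration
#'
#' The early- and late-delay windows are the first \code{earlySpan} and last
#' \code{lateSpan} seconds of the delay period; with the 5 s delay and 2 s
#' spans the late-delay window is delay seconds 4-5 (the seconds whose
#' inhibition degrades task performance), and the middle second of the delay
#' is left unassigned.
#'
#' @param config a [TaskConfig-class].
#' @param earlySpan,lateSpan spans (s) of the early- and late-delay windows;
#'   their sum may not exceed the delay duration.
#' @return An [EpochWindows-class] object.
#' @examples
#' epochWindows(taskConfig())  # late_delay = [4, 6) s after odour onset
#' @export
epochWindows <- function(config, earlySpan = 2, lateSpan = 2) {
  if (earlySpan <= 0 || lateSpan <= 0)
    stop("earlySpan and lateSpan must be > 0")
  if (earlySpan + lateSpan > config@delayDur + 1e-9)
    stop("earlySpan + lateSpan exceeds the delay duration")
  o1 <- config@odour1Dur
  dEnd <- o1 + config@delayDur
  w <- rbind(
    baseline     = c(-config@baselineDur, 0),
    first_odour  = c(0, o1),
    early_delay  = c(o1, o1 + earlySpan),
    late_delay   = c(dEnd - lateSpan, dEnd),
    second_odour = c(dEnd, dEnd + config@odour2Dur),
    choice       = c(dEnd + config@odour2Dur,
                     dEnd + config@odour2Dur + config@choiceDur)
  )
  colnames(w) <- c("start", "end")
  new("EpochWindows", windows = w)
}

#' Window of one epoch
#' @param windows an [EpochWindows-class].
#' @param epoch epoch name, one of [EPOCHS].
#' @return numeric \code{c(start, end)} in seconds.
#' @export
epochWindow <- function(windows, epoch) {
  if (!epoch %in% rownames(windows@windows))
    stop(sprintf("unknown epoch '%s'", epoch))
  windows@windows[epoch, ]
}

## Start times (s, relative to first-odour onset) of the frames of one trial.
frameStarts <- function(config) {
  n <- framesPerTrial(config)
  -config@baselineDur + (seq_len(n) - 1) / config@frameRate
}

binStartTimes <- function(config) {
  nBins <- floor(trialDuration(config) / config@binWidth + 1e-9)
  -config@baselineDur + (seq_len(nBins) - 1) * config@binWidth
}

#' Bin trial-aligned activity into fixed-width time bins
#'
#' Sums deconvolved event mass within 500 ms bins (by default). Frames are
#' assigned to the bin containing their start time; a trailing partial bin is
#' dropped so that all trials share the same shape. Summation (rather than
#' averaging) preserves event mass, the natural unit of deconvolved activity.
#'
#' @param session a [Session-class].
#' @param config a [TaskConfig-class]; its \code{frameRate} must match the
#'   session's.
#' @return A [TrialTensor-class].
#' @export
binActivity <- function(session, config) {
  act <- activityTensor(session)
  d <- dim(act)
  if (d[1] == 0 || d[2] == 0) stop("empty session: no trials or neurons")
  if (anyNA(act)) {
    idx <- which(is.na(act), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN activity at trial %d, neuron %s, frame %d",
                 idx[1], neuronIds(session)[idx[2]], idx[3]))
  }
  if (abs(session@frameRate - config@frameRate) > 1e-9)
    stop("config frameRate does not match the session")
  ts <- frameStarts(config)[seq_len(d[3])]
  bw <- config@binWidth
  nBins <- floor(trialDuration(config) / bw + 1e-9)
  binOf <- floor((ts + config@baselineDur) / bw + 1e-9) + 1
  keep <- binOf >= 1 & binOf <= nBins
  if (!any(keep)) stop("trial too short for a single bin")
  f <- factor(binOf[keep], levels = seq_len(nBins))
  ## rowsum over frames, applied to the [frame x (trial*neuron)] unfold
  flat <- matrix(aperm(act, c(3, 1, 2)), nrow = d[3])
  binned <- rowsum(flat[keep, , drop = FALSE], f)
  vals <- aperm(array(binned, dim = c(nBins, d[1], d[2])), c(2, 3, 1))
  new("TrialTensor", values = vals, binStarts = binStartTimes(config),
      binWidth = bw,
      sessionId = paste(animalId(session), dayIndex(session), sep = "/"))
}

## Indices of the bins whose start time lies in [start, end).
binsInWindow <- function(tensor, win) {
  which(tensor@binStarts >= win[1] - 1e-9 & tensor@binStarts < win[2] - 1e-9)
}

#' Per-trial, per-neuron mean activity over one epoch
#'
#' @param tensor a [TrialTensor-class].
#' @param windows an [EpochWindows-class].
#' @param epoch epoch name.
#' @return numeric matrix \code{[nTrials x nNeurons]} of mean bin values.
#' @export
epochMean <- function(tensor, windows, epoch) {
  bins <- binsInWindow(tensor, epochWindow(windows, epoch))
  if (!length(bins)) stop(sprintf("no bins fall inside epoch '%s'", epoch))
  v <- tensor@values[, , bins, drop = FALSE]
  apply(v, c(1, 2), mean)
}

#' Baseline-normalized trial-average response map
#'
#' Averages the binned activity across trials, subtracts each neuron's mean
#' baseline-epoch activity and divides by its baseline s.d., so the map is in
#' units of the s.d. of spontaneous activity. Neurons with zero baseline s.d.
#' (silent in the baseline) get an all-zero map and are flagged.
#'
#' @param tensor a [TrialTensor-class].
#' @param windows an [EpochWindows-class].
#' @return list with \code{map} (\code{[nBins x nNeurons]} z-scored trace),
#'   \code{baselineMean}, \code{baselineSd} and logical \code{flagged}.
#' @export
zscoreResponseMap <- function(tensor, windows, epoch = "baseline") {
  bins <- binsInWindow(tensor, epochWindow(windows, epoch))
  if (!length(bins)) stop("baseline window contains no bins")
  avg <- apply(tensor@values, c(3, 2), mean)           # bins x neurons
  mu <- colMeans(avg[bins, , drop = FALSE])
  sdv <- apply(avg[bins, , drop = FALSE], 2, stats::sd)
  flagged <- !is.finite(sdv) | sdv == 0
  z <- sweep(sweep(avg, 2, mu, "-"), 2, ifelse(flagged, 1, sdv), "/")
  z[, flagged] <- 0
  list(map = z, baselineMean = mu, baselineSd = sdv, flagged = flagged)
}
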