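## Behavioural performance metrics, stage labels and the session abort rule.

#' Early-abort rule for unmotivated sessions
#'
#' Scans outcomes in order and ends the session at the first trial where the
#' trailing window of (at most) ten trials contains more than three misses,
#' the criterion used to detect loss of motivation for the water reward.
#'
#' @param outcomes character vector of trial outcomes in presentation order
#'   (\code{"miss"} entries trigger the rule).
#' @return Number of completed trials (the aborting trial is the last one
#'   completed).
#' @examples
#' applyAbortRule(rep("hit", 20))  # 20
#' @export
applyAbortRule <- function(outcomes) {
  n <- length(outcomes)
  miss <- cumsum(outcomes == "miss")
  for (i in seq_len(n)) {
    lo <- max(0, i - 10)
    if (miss[i] - (if (lo > 0) miss[lo] else 0) >= 4) return(i)
  }
  n
}

#' Behavioural sensitivity (d-prime)
#'
#' Standard signal-detection discriminability \eqn{D' = \Phi^{-1}(H) -
#' \Phi^{-1}(F)}. Extreme rates (0 or 1) are corrected by the 1/(2N) rule so
#' the statistic stays finite: a rate of 1 becomes \eqn{1 - 1/(2N)} and a
#' rate of 0 becomes \eqn{1/(2N)}, with N the number of trials behind the
#' rate.
#'
#' @param hitRate,faRate hit and false-alarm rates in \code{[0, 1]}.
#' @param nSignal,nNoise trial counts behind each rate (used only for the
#'   extreme-rate correction).
#' @return D-prime (numeric scalar).
#' @examples
#' dprime(0.99, 0.01)       # about 4.65
#' dprime(1, 0, 50, 50)     # finite, via the 1/(2N) correction
#' @export
dprime <- function(hitRate, faRate, nSignal = 100, nNoise = 100) {
  stopifnot_scalar01(hitRate, "hitRate")
  stopifnot_scalar01(faRate, "faRate")
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clamp(hitRate, nSignal)) - stats::qnorm(clamp(faRate, nNoise))
}

#' Training-stage label from performance
#'
#' An animal is naive below 65% performance, training from 65% up to (but
#' excluding) 80%, and expert at 80% and above; novice marks the first
#' training day regardless of performance.
#'
#' @param p performance in \code{[0, 1]}.
#' @param dayIndex 1-based training day.
#' @return list with \code{stage} ("naive"/"training"/"expert") and logical
#'   \code{novice}.
#' @export
classifyStage <- function(p, dayIndex = 1L) {
  stopifnot_scalar01(p, "p")
  stage <- if (p < 0.65) "naive" else if (p < 0.80) "training" else "expert"
  list(stage = stage, novice = dayIndex == 1L)
}

#' Summarize behavioural performance of one session
#'
#' Counts outcomes over completed trials and computes performance (hits plus
#' correct rejections over completed trials), hit and false-alarm rates,
#' d-prime and the training-stage label.
#'
#' @param trials data.frame with an \code{outcome} column (and optionally
#'   \code{rewarded}); or a [Session-class].
#' @param dayIndex day used for the novice flag (taken from the session when
#'   one is supplied).
#' @return list with counts, \code{performance}, \code{hitRate},
#'   \code{faRate}, \code{dprime}, \code{stage}, \code{novice},
#'   \code{nCompleted}.
#' @export
behaviourSummary <- function(trials, dayIndex = 1L) {
  if (is(trials, "Session")) {
    dayIndex <- dayIndex(trials)
    trials <- trialTable(trials)
  }
  if (!nrow(trials)) stop("no completed trials")
  out <- trials$outcome
  hits <- sum(out == "hit"); miss <- sum(out == "miss")
  fa <- sum(out == "false_alarm"); cr <- sum(out == "correct_rejection")
  total <- hits + miss + fa + cr
  if (total != nrow(trials)) stop("unrecognized outcome labels present")
  p <- (hits + cr) / total
  nSig <- hits + miss; nNoi <- fa + cr
  H <- if (nSig > 0) hits / nSig else NA_real_
  F <- if (nNoi > 0) fa / nNoi else NA_real_
  D <- if (nSig > 0 && nNoi > 0) dprime(H, F, nSig, nNoi) else NA_real_
  st <- classifyStage(p, dayIndex)
  list(hits = hits, misses = miss, falseAlarms = fa, correctRejections = cr,
       nCompleted = total, performance = p, hitRate = H, faRate = F,
       dprime = D, stage = st$stage, novice = st$novice)
}

#' Per-day behaviour table for a cohort
#'
#' @param cohort a [Cohort-class].
#' @return data.frame with one row per session: animal, day, outcome counts,
#'   performance, d-prime and stage.
#' @export
cohortBehaviour <- function(cohort) {
  rows <- lapply(sessions(cohort), function(s) {
    b <- behaviourSummary(s)
    data.frame(animal = animalId(s), day = dayIndex(s), hits = b$hits,
               misses = b$misses, falseAlarms = b$falseAlarms,
               correctRejections = b$correctRejections,
               nCompleted = b$nCompleted, performance = b$performance,
               dprime = b$dprime, stage = b$stage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
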