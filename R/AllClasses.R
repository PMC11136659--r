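## Central S4 containers for the pipeline. Time convention throughout:
## trial time 0 = first-odour onset; windows are half-open [start, end);
## frames and bins are assigned to windows by their start time.

#' Epoch names used throughout the package
#'
#' The six task epochs of the delayed-association trial, in temporal order.
#' @export
EPOCHS <- c("baseline", "first_odour", "early_delay", "late_delay",
            "second_odour", "choice")

#' Task timing configuration
#'
#' Durations of the trial phases of the olfactory delayed-association task
#' (baseline, first odour, delay, second odour, choice), the imaging frame
#' rate and the analysis bin width. Defaults follow the task design: 5 s
#' baseline, 1 s odour, 5 s delay, 1 s second odour, 3 s choice window,
#' 10 Hz imaging, 500 ms bins.
#'
#' @slot baselineDur,odour1Dur,delayDur,odour2Dur,choiceDur phase durations
#'   in seconds; all strictly positive.
#' @slot frameRate imaging frame rate in Hz.
#' @slot binWidth analysis bin width in seconds.
#' @export
setClass("TaskConfig", representation(
  baselineDur = "numeric", odour1Dur = "numeric", delayDur = "numeric",
  odour2Dur = "numeric", choiceDur = "numeric",
  frameRate = "numeric", binWidth = "numeric"
))

setValidity("TaskConfig", function(object) {
  durs <- c(object@baselineDur, object@odour1Dur, object@delayDur,
            object@odour2Dur, object@choiceDur, object@frameRate,
            object@binWidth)
  if (any(!is.finite(durs)) || any(durs <= 0))
    return("all durations, frameRate and binWidth must be finite and > 0")
  TRUE
})

#' Construct a task timing configuration
#'
#' @param baselineDur,odour1Dur,delayDur,odour2Dur,choiceDur phase durations
#'   (seconds).
#' @param frameRate imaging frame rate (Hz).
#' @param binWidth analysis bin width (seconds).
#' @return A [TaskConfig-class] object.
#' @examples
#' cfg <- taskConfig()
#' trialDuration(cfg)  # 15 s
#' @export
taskConfig <- function(baselineDur = 5, odour1Dur = 1, delayDur = 5,
                       odour2Dur = 1, choiceDur = 3, frameRate = 10,
                       binWidth = 0.5) {
  new("TaskConfig", baselineDur = baselineDur, odour1Dur = odour1Dur,
      delayDur = delayDur, odour2Dur = odour2Dur, choiceDur = choiceDur,
      frameRate = frameRate, binWidth = binWidth)
}

#' Total trial duration in seconds
#' @param config a [TaskConfig-class].
#' @export
trialDuration <- function(config) {
  config@baselineDur + config@odour1Dur + config@delayDur +
    config@odour2Dur + config@choiceDur
}

#' Frames per trial implied by a task configuration
#' @param config a [TaskConfig-class].
#' @export
framesPerTrial <- function(config) {
  n <- trialDuration(config) * config@frameRate
  if (abs(n - round(n)) > 1e-6)
    n <- floor(n + 1e-9)
  as.integer(round(n))
}

setMethod("show", "TaskConfig", function(object) {
  cat("TaskConfig:", object@baselineDur, "s baseline |",
      object@odour1Dur, "s odour1 |", object@delayDur, "s delay |",
      object@odour2Dur, "s odour2 |", object@choiceDur, "s choice;",
      object@frameRate, "Hz,", object@binWidth * 1000, "ms bins\n")
})

#' Named task-epoch windows
#'
#' Maps the six epoch names to half-open time windows \code{[start, end)} in
#' seconds relative to first-odour onset.
#'
#' @slot windows numeric matrix with rownames [EPOCHS] and columns
#'   \code{start}, \code{end}.
#' @export
setClass("EpochWindows", representation(windows = "matrix"))

setValidity("EpochWindows", function(object) {
  w <- object@windows
  if (!is.numeric(w) || ncol(w) != 2 || !setequal(rownames(w), EPOCHS))
    return("windows must be a numeric matrix with one row per epoch")
  if (any(w[, 2] <= w[, 1])) return("each window must satisfy start < end")
  TRUE
})

setMethod("show", "EpochWindows", function(object) {
  w <- object@windows
  cat("EpochWindows (s, relative to first-odour onset):\n")
  for (e in EPOCHS)
    cat(sprintf("  %-12s [%5.2f, %5.2f)\n", e, w[e, 1], w[e, 2]))
})

#' One trial-aligned recording session
#'
#' One day's recording from one animal: an ordered trial table, the
#' trial-aligned deconvolved activity tensor, neuron identifiers, centroid
#' geometry and an optional locomotion trace.
#'
#' @slot animalId animal identifier.
#' @slot dayIndex 1-based day index.
#' @slot trials data.frame with columns \code{trialType} (AC/AD/BC/BD),
#'   \code{firstOdour}, \code{secondOdour}, \code{rewarded}, \code{licked},
#'   \code{outcome} (hit/miss/false_alarm/correct_rejection) and optionally
#'   \code{isError}.
#' @slot activity numeric array \code{[nTrials x nNeurons x nFrames]} of
#'   nonnegative deconvolved event amplitudes.
#' @slot neuronIds character vector, unique within the session.
#' @slot centroids data.frame with columns \code{x}, \code{y}, \code{depth}
#'   in micrometres.
#' @slot locomotion per-frame speed trace for the concatenated session
#'   (length 0 if absent).
#' @slot frameRate imaging frame rate of this session (Hz).
#' @export
setClass("Session", representation(
  animalId = "character", dayIndex = "integer", trials = "data.frame",
  activity = "array", neuronIds = "character", centroids = "data.frame",
  locomotion = "numeric", frameRate = "numeric"
))

setValidity("Session", function(object) {
  d <- dim(object@activity)
  if (length(d) != 3) return("activity must be a 3-d array")
  if (d[1] != nrow(object@trials))
    return("activity dim 1 must equal the number of trials")
  if (d[2] != length(object@neuronIds))
    return("activity dim 2 must equal the number of neuronIds")
  if (anyDuplicated(object@neuronIds))
    return("neuronIds must be unique within a session")
  if (nrow(object@centroids) != d[2])
    return("centroids must have one row per neuron")
  if (any(object@activity < 0, na.rm = TRUE))
    return("deconvolved activity must be nonnegative")
  req <- c("trialType", "firstOdour", "secondOdour", "rewarded", "licked",
           "outcome")
  miss <- setdiff(req, names(object@trials))
  if (length(miss)) return(paste("trials is missing column:", miss[1]))
  TRUE
})

newSession <- function(animalId, dayIndex, trials, activity, neuronIds,
                       centroids, locomotion = numeric(0), frameRate = 10) {
  new("Session", animalId = as.character(animalId),
      dayIndex = as.integer(dayIndex), trials = trials, activity = activity,
      neuronIds = as.character(neuronIds), centroids = centroids,
      locomotion = locomotion, frameRate = frameRate)
}

setMethod("nTrials", "Session", function(x) dim(x@activity)[1])
setMethod("nNeurons", "Session", function(x) dim(x@activity)[2])
setMethod("trialTable", "Session", function(x) x@trials)
setMethod("activityTensor", "Session", function(x) x@activity)
setMethod("centroids", "Session", function(x) x@centroids)
setMethod("animalId", "Session", function(x) x@animalId)
setMethod("dayIndex", "Session", function(x) x@dayIndex)
setMethod("neuronIds", "Session", function(x) x@neuronIds)

setMethod("show", "Session", function(object) {
  cat(sprintf("Session: animal %s, day %d — %d trials x %d neurons x %d frames (%.3g Hz)\n",
              object@animalId, object@dayIndex, dim(object@activity)[1],
              dim(object@activity)[2], dim(object@activity)[3],
              object@frameRate))
})

#' Multi-animal, multi-day cohort
#'
#' A list of [Session-class] objects grouped by animal and day, together with
#' the planted ground-truth tuning table when the cohort is synthetic.
#'
#' @slot sessions list of [Session-class] objects.
#' @slot groundTruth data.frame of planted tuning (one row per animal x day x
#'   neuron; empty for real data).
#' @slot config list snapshot of the generator configuration (may be empty).
#' @export
setClass("Cohort", representation(
  sessions = "list", groundTruth = "data.frame", config = "list"
))

setValidity("Cohort", function(object) {
  if (!all(vapply(object@sessions, is, logical(1), "Session")))
    return("all elements of sessions must be Session objects")
  TRUE
})

setMethod("sessions", "Cohort", function(x) x@sessions)
setMethod("groundTruth", "Cohort", function(x) x@groundTruth)

setMethod("show", "Cohort", function(object) {
  an <- vapply(object@sessions, animalId, character(1))
  cat(sprintf("Cohort: %d sessions, %d animals%s\n",
              length(object@sessions), length(unique(an)),
              if (nrow(object@groundTruth)) " (synthetic, ground truth attached)"
              else ""))
})

#' Select the sessions of one animal, ordered by day
#' @param cohort a [Cohort-class].
#' @param animal animal identifier.
#' @return list of [Session-class], ordered by \code{dayIndex}.
#' @export
animalSessions <- function(cohort, animal) {
  ss <- Filter(function(s) animalId(s) == animal, sessions(cohort))
  ss[order(vapply(ss, dayIndex, integer(1)))]
}

#' Animal identifiers present in a cohort
#' @param cohort a [Cohort-class].
#' @export
cohortAnimals <- function(cohort) {
  unique(vapply(sessions(cohort), animalId, character(1)))
}

#' Binned trial-aligned activity
#'
#' Trial x neuron x bin tensor obtained by summing deconvolved event mass in
#' fixed-width time bins (see [binActivity]).
#'
#' @slot values numeric array \code{[nTrials x nNeurons x nBins]}.
#' @slot binStarts bin start times (s, relative to first-odour onset).
#' @slot binWidth bin width (s).
#' @slot sessionId provenance string.
#' @export
setClass("TrialTensor", representation(
  values = "array", binStarts = "numeric", binWidth = "numeric",
  sessionId = "character"
))

setValidity("TrialTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-d array")
  if (d[3] != length(object@binStarts))
    return("binStarts must have one entry per bin")
  if (any(object@values < 0, na.rm = TRUE))
    return("binned activity must be nonnegative")
  TRUE
})

setMethod("nTrials", "TrialTensor", function(x) dim(x@values)[1])
setMethod("nNeurons", "TrialTensor", function(x) dim(x@values)[2])

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("TrialTensor: %d trials x %d neurons x %d bins (%d ms)\n",
              d[1], d[2], d[3], round(object@binWidth * 1000)))
})

#' Day-by-day decoder generalization matrix
#'
#' \code{acc[i, j]} holds the accuracy of a decoder trained on day \code{i}
#' and tested on day \code{j} using neurons matched across the pair; the
#' diagonal holds same-day cross-validated accuracy so on- and off-diagonal
#' entries are comparable.
#'
#' @slot acc numeric day x day matrix of accuracies in \code{[0, 1]}
#'   (NA where a pair had too few matched neurons).
#' @slot nMatched integer matrix of matched-neuron counts per pair.
#' @slot days day indices labelling rows/columns.
#' @slot epoch epoch decoded.
#' @slot labelSet label set decoded ("first_odour", "choice", "category").
#' @slot animalId animal identifier.
#' @export
setClass("CrossDayMatrix", representation(
  acc = "matrix", nMatched = "matrix", days = "integer", epoch = "character",
  labelSet = "character", animalId = "character"
))

setValidity("CrossDayMatrix", function(object) {
  if (!all(dim(object@acc) == length(object@days)))
    return("acc must be square with one row per day")
  ok <- object@acc[!is.na(object@acc)]
  if (length(ok) && (any(ok < 0) || any(ok > 1)))
    return("accuracies must lie in [0, 1]")
  TRUE
})

setMethod("show", "CrossDayMatrix", function(object) {
  cat(sprintf("CrossDayMatrix: animal %s, %s / %s, days %d-%d\n",
              object@animalId, object@labelSet, object@epoch,
              min(object@days), max(object@days)))
  print(round(object@acc, 3))
})
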