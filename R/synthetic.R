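## Synthetic-cohort generator: planted tuning, drift/crystallization
## schedules, depth gradients, behavioural errors, and the ground truth
## needed for parameter recovery.

ODOUR1_EPOCHS <- c("first_odour", "early_delay", "late_delay")

#' Generator configuration
#'
#' Describes the statistical structure of a synthetic cohort. Event activity
#' is a compound Poisson process: per-frame event counts are Poisson with a
#' rate set by tuning, each event carrying an exponential(mean 1) amplitude,
#' which mimics sparse nonnegative deconvolved calcium events. Rates are
#' expressed as expected event mass per analysis bin (see
#' \code{task@binWidth}).
#'
#' Tuning is planted per neuron per day. Day-to-day, a selective neuron keeps
#' its tuning with probability \code{retention}; otherwise its tuning is
#' redrawn from the day-one marginal scheme (so some neurons gain and others
#' lose responsiveness while population fractions stay constant). From
#' \code{crystallizationDay} onward the retention probability is 1 and the
#' code is frozen.
#'
#' @param nAnimals,nDays,nNeurons,trialsPerDay cohort dimensions. Sessions
#'   hold 150-250 trials in the emulated task; the default plants 200.
#' @param fracSelective named fractions of neurons whose primary informative
#'   epoch is each of first_odour, early_delay, late_delay, second_odour,
#'   choice; must sum to at most 1. Counts on day one are
#'   \code{floor(frac * nNeurons)}, assigned deterministically by neuron
#'   index.
#' @param mixedProb probability that a selective neuron carries one or two
#'   additional informative epochs (mixed selectivity).
#' @param pairFrac fraction of neurons planted as associated-pair cells
#'   (selective for both rewarded odours A and C, or B and D).
#' @param effectRateHi,effectRateLo expected event mass per bin in the
#'   informative epoch on preferred / non-preferred trials.
#' @param noiseRate baseline event mass per bin outside informative epochs.
#' @param retention day-to-day tuning retention probability before
#'   crystallization.
#' @param crystallizationDay first day from which tuning is frozen
#'   (\code{nDays + 1} disables stabilization).
#' @param depthRange depth extent of the imaged volume (micrometres).
#' @param depthGradient logistic slope (per micrometre) of the probability
#'   that a selective neuron's informative epoch is late_delay; 0 plants no
#'   gradient.
#' @param carryOverProb probability that an odour-1-selective neuron's
#'   elevated rate persists through the second-odour epoch (a persistent
#'   working-memory trace, which is what makes the four trial categories
#'   separable during the second odour).
#' @param errorRate probability that the animal responds incorrectly on a
#'   trial.
#' @param errorDegrade fraction of the late-delay effect removed on error
#'   trials (1 = late-delay code fully absent when the animal errs).
#' @param detectionDropout per-day probability that a neuron goes undetected.
#' @param centroidJitter s.d. (micrometres) of day-to-day centroid jitter.
#' @param fieldSize lateral extent (micrometres) of the imaged field.
#' @param applyAbort apply the miss-based early-abort rule when simulating
#'   behaviour.
#' @param task a [TaskConfig-class].
#' @return list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(nAnimals = 4, nDays = 10, nNeurons = 500,
                            trialsPerDay = 200,
                            fracSelective = c(first_odour = 0.15,
                                              early_delay = 0.08,
                                              late_delay = 0.10,
                                              second_odour = 0.08,
                                              choice = 0.15),
                            mixedProb = 0.4, pairFrac = 0.012,
                            effectRateHi = 0.6, effectRateLo = 0.2,
                            noiseRate = 0.2,
                            retention = 0.5,
                            crystallizationDay = min(6, nDays + 1),
                            depthRange = c(30, 450), depthGradient = 0,
                            carryOverProb = 0.3,
                            errorRate = 0.06, errorDegrade = 1,
                            detectionDropout = 0, centroidJitter = 1,
                            fieldSize = 2000, applyAbort = TRUE,
                            task = taskConfig()) {
  cfg <- list(nAnimals = nAnimals, nDays = nDays, nNeurons = nNeurons,
              trialsPerDay = trialsPerDay, fracSelective = fracSelective,
              mixedProb = mixedProb, pairFrac = pairFrac,
              effectRateHi = effectRateHi, effectRateLo = effectRateLo,
              noiseRate = noiseRate, retention = retention,
              crystallizationDay = crystallizationDay,
              depthRange = depthRange, depthGradient = depthGradient,
              carryOverProb = carryOverProb,
              errorRate = errorRate, errorDegrade = errorDegrade,
              detectionDropout = detectionDropout,
              centroidJitter = centroidJitter, fieldSize = fieldSize,
              applyAbort = applyAbort, task = task)
  class(cfg) <- "GeneratorConfig"
  validateGeneratorConfig(cfg)
  cfg
}

validateGeneratorConfig <- function(cfg) {
  chkPos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1)
      stop(sprintf("invalid GeneratorConfig field '%s': must be >= 1", field),
           call. = FALSE)
  }
  for (f in c("nAnimals", "nDays", "nNeurons", "trialsPerDay")) chkPos(f)
  fs <- cfg$fracSelective
  if (is.null(names(fs)) || !all(names(fs) %in% setdiff(EPOCHS, "baseline")))
    stop("invalid GeneratorConfig field 'fracSelective': names must be task epochs",
         call. = FALSE)
  if (any(fs < 0) || sum(fs) > 1)
    stop("invalid GeneratorConfig field 'fracSelective': fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  for (f in c("mixedProb", "pairFrac", "retention", "errorRate",
              "errorDegrade", "detectionDropout", "carryOverProb")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid GeneratorConfig field '%s': must be in [0, 1]", f),
           call. = FALSE)
  }
  for (f in c("effectRateHi", "effectRateLo", "noiseRate", "centroidJitter"))
    if (cfg[[f]] < 0)
      stop(sprintf("invalid GeneratorConfig field '%s': must be >= 0", f),
           call. = FALSE)
  if (cfg$crystallizationDay > cfg$nDays + 1)
    stop("invalid GeneratorConfig field 'crystallizationDay': must be <= nDays + 1",
         call. = FALSE)
  invisible(TRUE)
}

#' Simulate a behavioural trial sequence
#'
#' Trial types are drawn uniformly at random (odour combinations are
#' presented in random order); the animal responds correctly except on error
#' trials (probability \code{errorRate}), where its lick decision is
#' inverted. Optionally the miss-based early-abort rule truncates the
#' session.
#'
#' @param nTrials number of scheduled trials.
#' @param errorRate per-trial error probability.
#' @param applyAbort apply [applyAbortRule] and truncate.
#' @return data.frame of completed trials with columns trialType, firstOdour,
#'   secondOdour, rewarded, licked, outcome, isError.
#' @export
simulateBehaviour <- function(nTrials, errorRate = 0.06, applyAbort = TRUE) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  tt <- sample(c("AC", "AD", "BC", "BD"), nTrials, replace = TRUE)
  first <- substr(tt, 1, 1)
  second <- substr(tt, 2, 2)
  rewarded <- tt %in% c("AC", "BD")
  isError <- stats::runif(nTrials) < errorRate
  licked <- ifelse(isError, !rewarded, rewarded)
  outcome <- ifelse(rewarded,
                    ifelse(licked, "hit", "miss"),
                    ifelse(licked, "false_alarm", "correct_rejection"))
  df <- data.frame(trialType = tt, firstOdour = first, secondOdour = second,
                   rewarded = rewarded, licked = licked, outcome = outcome,
                   isError = isError, stringsAsFactors = FALSE)
  if (applyAbort) df <- df[seq_len(applyAbortRule(df$outcome)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Probability, per selective neuron, that its primary epoch is late_delay
## under the planted depth gradient.
lateDelayProb <- function(cfg, depth) {
  mid <- mean(cfg$depthRange)
  stats::plogis(cfg$depthGradient * (depth - mid))
}

## Draw a tuning table for a set of neurons. exact = TRUE plants
## floor(frac * n) neurons per primary epoch deterministically by neuron
## index (day-one assignment); exact = FALSE redraws i.i.d. from the same
## marginal scheme (day-to-day resampling).
drawTuning <- function(cfg, depths, exact) {
  n <- length(depths)
  fs <- cfg$fracSelective
  eps <- names(fs)
  primary <- rep(NA_character_, n)
  if (exact) {
    at <- 1L
    for (e in eps) {
      k <- floor(fs[[e]] * n)
      if (k > 0) { primary[at:(at + k - 1L)] <- e; at <- at + k }
    }
  } else {
    u <- stats::runif(n)
    cuts <- cumsum(fs)
    for (i in seq_len(n)) {
      j <- which(u[i] < cuts)
      if (length(j)) primary[i] <- eps[j[1]]
    }
  }
  sel <- !is.na(primary)
  if (cfg$depthGradient != 0 && any(sel)) {
    ## reassign primary epochs of selective neurons so the late-delay
    ## probability follows the planted depth gradient
    pl <- lateDelayProb(cfg, depths[sel])
    others <- setdiff(eps, "late_delay")
    w <- fs[others]; w <- w / sum(w)
    isLate <- stats::runif(sum(sel)) < pl
    newPrim <- ifelse(isLate, "late_delay",
                      sample(others, sum(sel), replace = TRUE, prob = w))
    primary[sel] <- newPrim
  }
  epochs <- vector("list", n)
  for (i in which(sel)) {
    ep <- primary[i]
    if (stats::runif(1) < cfg$mixedProb) {
      k <- sample(1:2, 1)
      extra <- sample(setdiff(eps, ep), min(k, length(eps) - 1))
      ep <- c(ep, extra)
    }
    epochs[[i]] <- ep
  }
  ## associated-pair cells: selective for both rewarded odours (A&C or B&D)
  pair <- rep(FALSE, n)
  if (cfg$pairFrac > 0) {
    if (exact) {
      k <- floor(cfg$pairFrac * n)
      cand <- rev(which(!sel))
      take <- cand[seq_len(min(k, length(cand)))]
      pair[take] <- TRUE
    } else {
      pair[!sel & stats::runif(n) < cfg$pairFrac] <- TRUE
    }
    for (i in which(pair)) epochs[[i]] <- c("first_odour", "second_odour")
  }
  prefO1 <- rep(NA_character_, n)
  prefO2 <- rep(NA_character_, n)
  prefCh <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ep <- epochs[[i]]
    if (is.null(ep)) next
    if (pair[i]) {
      prefO1[i] <- sample(c("A", "B"), 1)
      prefO2[i] <- if (prefO1[i] == "A") "C" else "D"
    } else {
      if (any(ep %in% ODOUR1_EPOCHS)) prefO1[i] <- sample(c("A", "B"), 1)
      if ("second_odour" %in% ep) prefO2[i] <- sample(c("C", "D"), 1)
      if ("choice" %in% ep) prefCh[i] <- sample(c("lick", "nolick"), 1)
    }
  }
  hasO1 <- vapply(epochs, function(e) any(e %in% ODOUR1_EPOCHS), logical(1))
  data.frame(
    selective = !vapply(epochs, is.null, logical(1)),
    epochs = vapply(epochs, function(e) paste(e, collapse = ";"), character(1)),
    prefOdour1 = prefO1, prefOdour2 = prefO2, prefChoice = prefCh,
    pairCell = pair,
    persistent = hasO1 & stats::runif(n) < cfg$carryOverProb,
    stringsAsFactors = FALSE)
}

## Advance a tuning table by one day transition with retention rho.
advanceTuning <- function(tun, cfg, depths, rho) {
  if (rho >= 1) return(tun)
  redraw <- stats::runif(nrow(tun)) >= rho
  if (!any(redraw)) return(tun)
  fresh <- drawTuning(cfg, depths, exact = FALSE)
  tun[redraw, ] <- fresh[redraw, ]
  tun
}

## Per-frame Poisson rates for one session given the tuning table; then one
## compound Poisson-exponential draw per frame.
sessionActivity <- function(cfg, tun, trials, windows) {
  task <- cfg$task
  nT <- nrow(trials); nN <- nrow(tun); nF <- framesPerTrial(task)
  perFrame <- 1 / (task@frameRate * task@binWidth)  # bin mass -> frame rate
  ts <- frameStarts(task)
  rates <- array(cfg$noiseRate * perFrame, dim = c(nT, nN, nF))
  hiF <- cfg$effectRateHi * perFrame
  loF <- cfg$effectRateLo * perFrame
  for (j in which(tun$selective)) {
    eps <- strsplit(tun$epochs[j], ";", fixed = TRUE)[[1]]
    ## persistent odour-1 trace extends into the second-odour epoch unless
    ## the neuron has its own explicit second-odour tuning there
    if (tun$persistent[j] && !"second_odour" %in% eps) {
      win <- epochWindow(windows, "second_odour")
      fr <- which(ts >= win[1] - 1e-9 & ts < win[2] - 1e-9)
      pref <- trials$firstOdour == tun$prefOdour1[j]
      rates[, j, fr] <- ifelse(pref, hiF, loF)
    }
    for (e in eps) {
      win <- epochWindow(windows, e)
      fr <- which(ts >= win[1] - 1e-9 & ts < win[2] - 1e-9)
      pref <- switch(
        e,
        first_odour = , early_delay = , late_delay =
          trials$firstOdour == tun$prefOdour1[j],
        second_odour = trials$secondOdour == tun$prefOdour2[j],
        choice = trials$licked == (tun$prefChoice[j] == "lick"))
      if (tun$pairCell[j] && e %in% c("first_odour", "second_odour")) {
        pref <- if (e == "first_odour") trials$firstOdour == tun$prefOdour1[j]
                else trials$secondOdour == tun$prefOdour2[j]
      }
      hiTrial <- ifelse(pref, hiF, loF)
      if (e == "late_delay" && cfg$errorDegrade > 0 && any(trials$isError)) {
        deg <- trials$isError & pref
        hiTrial[deg] <- loF + (hiF - loF) * (1 - cfg$errorDegrade)
      }
      rates[, j, fr] <- hiTrial
    }
  }
  counts <- stats::rpois(length(rates), rates)
  vals <- numeric(length(counts))
  pos <- counts > 0
  vals[pos] <- stats::rgamma(sum(pos), shape = counts[pos], rate = 1)
  array(vals, dim = dim(rates))
}

#' Generate a synthetic multi-animal, multi-day cohort
#'
#' Plants tuning per neuron per day under the drift/crystallization schedule
#' of \code{config}, simulates behaviour (with errors and optionally the
#' abort rule), draws compound-Poisson event activity, jitters centroids
#' day-to-day, and records the planted ground truth for parameter recovery.
#'
#' @param config a \code{GeneratorConfig} from [generatorConfig].
#' @param seed integer master seed; the cohort is a deterministic function of
#'   (config, seed).
#' @return A [Cohort-class] with the ground-truth table attached.
#' @examples
#' cfg <- generatorConfig(nAnimals = 1, nDays = 2, nNeurons = 30,
#'                        trialsPerDay = 20)
#' coh <- generateCohort(cfg, seed = 1)
#' coh
#' @export
generateCohort <- function(config, seed = 1L) {
  validateGeneratorConfig(config)
  windows <- epochWindows(config$task)
  sess <- list()
  gt <- list()
  for (a in seq_len(config$nAnimals)) {
    withSeed(childSeed(seed, a), {
      aId <- sprintf("m%02d", a)
      n <- config$nNeurons
      ids <- sprintf("%s_n%04d", aId, seq_len(n))
      base <- data.frame(
        x = stats::runif(n, 0, config$fieldSize),
        y = stats::runif(n, 0, config$fieldSize),
        depth = stats::runif(n, config$depthRange[1], config$depthRange[2]))
      tun <- drawTuning(config, base$depth, exact = TRUE)
      for (d in seq_len(config$nDays)) {
        if (d > 1) {
          rho <- if ((d - 1) >= config$crystallizationDay) 1
                 else config$retention
          tun <- advanceTuning(tun, config, base$depth, rho)
        }
        trials <- simulateBehaviour(config$trialsPerDay, config$errorRate,
                                    config$applyAbort)
        act <- sessionActivity(config, tun, trials, windows)
        cent <- base + matrix(stats::rnorm(3 * n, 0, config$centroidJitter),
                              ncol = 3, dimnames = list(NULL, NULL))
        names(cent) <- c("x", "y", "depth")
        detected <- stats::runif(n) >= config$detectionDropout
        keep <- which(detected)
        loco <- abs(stats::filter(stats::rnorm(nrow(trials) *
                                                 framesPerTrial(config$task)),
                                  0.9, method = "recursive"))
        sess[[length(sess) + 1L]] <- newSession(
          aId, d, trials, act[, keep, , drop = FALSE], ids[keep],
          cent[keep, , drop = FALSE], as.numeric(loco),
          config$task@frameRate)
        gt[[length(gt) + 1L]] <- data.frame(
          animal = aId, day = d, neuronId = ids, selective = tun$selective,
          epochs = tun$epochs, prefOdour1 = tun$prefOdour1,
          prefOdour2 = tun$prefOdour2, prefChoice = tun$prefChoice,
          pairCell = tun$pairCell, persistent = tun$persistent,
          depth = base$depth, detected = detected,
          stringsAsFactors = FALSE)
      }
    })
  }
  cfgSnapshot <- unclass(config)
  cfgSnapshot$task <- NULL
  new("Cohort", sessions = sess, groundTruth = do.call(rbind, gt),
      config = cfgSnapshot)
}

#' Summaries of the planted ground truth
#'
#' Per-day selective fractions by epoch, the day-to-day tuning overlap
#' (fraction of neurons selective for an epoch on day d that keep the same
#' epoch and preferred label on day d+1 — equal to the retention probability
#' in expectation, plus the chance-redraw rate), and per-session error-trial
#' counts.
#'
#' @param cohort a synthetic [Cohort-class].
#' @return list with data.frames \code{fractions} (animal, day, epoch,
#'   fraction), \code{overlap} (animal, day transition, epoch, overlap) and
#'   \code{errors} (animal, day, nError, nCompleted).
#' @export
groundTruthSummary <- function(cohort) {
  gt <- groundTruth(cohort)
  if (!nrow(gt)) stop("cohort carries no ground truth")
  eps <- setdiff(EPOCHS, "baseline")
  hasEpoch <- function(df, e) {
    vapply(strsplit(df$epochs, ";", fixed = TRUE), function(s) e %in% s,
           logical(1))
  }
  prefOf <- function(df, e) {
    switch(e, first_odour = , early_delay = , late_delay = df$prefOdour1,
           second_odour = df$prefOdour2, choice = df$prefChoice)
  }
  fr <- list(); ov <- list()
  for (a in unique(gt$animal)) {
    ga <- gt[gt$animal == a, ]
    days <- sort(unique(ga$day))
    for (d in days) {
      gd <- ga[ga$day == d, ]
      for (e in eps)
        fr[[length(fr) + 1L]] <- data.frame(
          animal = a, day = d, epoch = e,
          fraction = mean(hasEpoch(gd, e)), stringsAsFactors = FALSE)
    }
    for (d in days[-length(days)]) {
      g1 <- ga[ga$day == d, ]; g2 <- ga[ga$day == d + 1, ]
      g2 <- g2[match(g1$neuronId, g2$neuronId), ]
      for (e in eps) {
        tuned <- hasEpoch(g1, e)
        if (!any(tuned)) next
        kept <- hasEpoch(g2, e) & !is.na(prefOf(g2, e)) &
          prefOf(g2, e) == prefOf(g1, e)
        ov[[length(ov) + 1L]] <- data.frame(
          animal = a, fromDay = d, epoch = e,
          overlap = sum(tuned & kept) / sum(tuned), stringsAsFactors = FALSE)
      }
    }
  }
  err <- do.call(rbind, lapply(sessions(cohort), function(s) {
    tr <- trialTable(s)
    data.frame(animal = animalId(s), day = dayIndex(s),
               nError = sum(tr$isError %||% FALSE),
               nCompleted = nrow(tr), stringsAsFactors = FALSE)
  }))
  list(fractions = do.call(rbind, fr), overlap = do.call(rbind, ov),
       errors = err)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
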