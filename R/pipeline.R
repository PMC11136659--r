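## Cohort container I/O (plain-text directory layout), pipeline
## orchestration and the summary report.

#' Write a cohort to a plain-text directory container
#'
#' Layout: \code{cohort.json} (session index and generator-config snapshot),
#' \code{ground_truth.csv}, and one directory per session holding
#' \code{trials.csv}, \code{activity.csv} (rows = trial x frame, one column
#' per neuron), \code{centroids.csv} and \code{locomotion.csv}. All values
#' are written in full precision so a read/write round trip is the identity.
#'
#' @param cohort a [Cohort-class].
#' @param path output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  idx <- lapply(sessions(cohort), function(s) {
    list(animal = animalId(s), day = dayIndex(s), frameRate = s@frameRate,
         dir = sprintf("%s_d%02d", animalId(s), dayIndex(s)))
  })
  jsonlite::write_json(list(sessions = idx, config = cohort@config),
                       file.path(path, "cohort.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  gt <- groundTruth(cohort)
  if (nrow(gt)) utils::write.csv(gt, file.path(path, "ground_truth.csv"),
                                 row.names = FALSE)
  for (s in sessions(cohort)) {
    d <- file.path(path, "sessions", sprintf("%s_d%02d", animalId(s),
                                             dayIndex(s)))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trialTable(s), file.path(d, "trials.csv"),
                     row.names = FALSE)
    cen <- centroids(s); cen$neuronId <- neuronIds(s)
    utils::write.csv(cen, file.path(d, "centroids.csv"), row.names = FALSE)
    act <- activityTensor(s)
    dd <- dim(act)
    flat <- matrix(aperm(act, c(3, 1, 2)), nrow = dd[1] * dd[3])
    colnames(flat) <- neuronIds(s)
    df <- data.frame(trial = rep(seq_len(dd[1]), each = dd[3]),
                     frame = rep(seq_len(dd[3]), dd[1]))
    utils::write.csv(cbind(df, flat), file.path(d, "activity.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(speed = s@locomotion),
                     file.path(d, "locomotion.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort written by [writeCohort]
#'
#' @param path container directory.
#' @return A [Cohort-class].
#' @export
readCohort <- function(path) {
  metaFile <- file.path(path, "cohort.json")
  if (!file.exists(metaFile)) stop(sprintf("missing file: %s", metaFile))
  meta <- jsonlite::read_json(metaFile)
  gtFile <- file.path(path, "ground_truth.csv")
  gt <- if (file.exists(gtFile))
    utils::read.csv(gtFile, stringsAsFactors = FALSE) else data.frame()
  ss <- lapply(meta$sessions, function(m) {
    d <- file.path(path, "sessions", m$dir)
    for (f in c("trials.csv", "activity.csv", "centroids.csv")) {
      if (!file.exists(file.path(d, f)))
        stop(sprintf("missing file: %s", file.path(d, f)))
    }
    trials <- utils::read.csv(file.path(d, "trials.csv"),
                              stringsAsFactors = FALSE)
    req <- c("trialType", "firstOdour", "secondOdour", "rewarded", "licked",
             "outcome")
    miss <- setdiff(req, names(trials))
    if (length(miss))
      stop(sprintf("missing column '%s' in %s", miss[1],
                   file.path(d, "trials.csv")))
    cen <- utils::read.csv(file.path(d, "centroids.csv"),
                           stringsAsFactors = FALSE)
    ids <- cen$neuronId
    cen <- cen[, setdiff(names(cen), "neuronId"), drop = FALSE]
    aw <- utils::read.csv(file.path(d, "activity.csv"), check.names = FALSE)
    nT <- max(aw$trial); nF <- max(aw$frame)
    flat <- as.matrix(aw[, !(names(aw) %in% c("trial", "frame")),
                         drop = FALSE])
    act <- aperm(array(flat, dim = c(nF, nT, ncol(flat))), c(2, 3, 1))
    locoFile <- file.path(d, "locomotion.csv")
    loco <- if (file.exists(locoFile))
      utils::read.csv(locoFile)$speed else numeric(0)
    newSession(m$animal, m$day, trials, act, ids, cen,
               as.numeric(loco %||% numeric(0)), m$frameRate)
  })
  new("Cohort", sessions = ss, groundTruth = gt,
      config = lapply(meta$config, unlist))
}

PIPELINE_STAGES <- c("simulate", "behaviour", "selectivity", "registration",
                     "decoding", "stability")

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> behaviour -> selectivity ->
#' registration -> decoding -> stability on a cohort, writing one CSV (or
#' JSON) per stage plus a run manifest. All randomness derives from the
#' single master seed, so a rerun with the same seed writes byte-identical
#' CSV outputs.
#'
#' @param genConfig a \code{GeneratorConfig} (used when \code{cohort} is
#'   NULL and "simulate" is among the stages).
#' @param cohort an existing [Cohort-class] to analyse instead of
#'   simulating.
#' @param outDir output directory.
#' @param seed master seed.
#' @param stages subset of \code{PIPELINE_STAGES} to run.
#' @param decCfg a \code{DecodingConfig}.
#' @param epochsDecoded epochs decoded in the decoding stage.
#' @param earlyDays,lateDays blocks for the stability stage (defaults:
#'   first and last halves of the day range).
#' @return list manifest (also written as \code{manifest.json}).
#' @export
runPipeline <- function(genConfig = generatorConfig(), cohort = NULL,
                        outDir, seed = 1L, stages = PIPELINE_STAGES,
                        decCfg = decodingConfig(),
                        epochsDecoded = c("first_odour", "choice"),
                        earlyDays = NULL, lateDays = NULL) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  task <- genConfig$task
  windows <- epochWindows(task)
  ran <- character(0)
  if ("simulate" %in% stages && is.null(cohort)) {
    cohort <- generateCohort(genConfig, seed = childSeed(seed, 1))
    ran <- c(ran, "simulate")
  }
  if (is.null(cohort)) stop("stage 'simulate' skipped but no cohort supplied")
  animals <- cohortAnimals(cohort)
  days <- sort(unique(vapply(sessions(cohort), dayIndex, integer(1))))
  if (is.null(earlyDays)) earlyDays <- days[seq_len(floor(length(days) / 2))]
  if (is.null(lateDays)) lateDays <- setdiff(days, earlyDays)

  if ("behaviour" %in% stages) {
    utils::write.csv(cohortBehaviour(cohort),
                     file.path(outDir, "behaviour.csv"), row.names = FALSE)
    ran <- c(ran, "behaviour")
  }
  if ("selectivity" %in% stages) {
    sel <- do.call(rbind, lapply(sessions(cohort), function(s) {
      g <- selectivityGrid(s, task, windows)
      cbind(animal = animalId(s), day = dayIndex(s), g)
    }))
    utils::write.csv(sel, file.path(outDir, "selectivity.csv"),
                     row.names = FALSE)
    prof <- do.call(rbind, lapply(split(sel, list(sel$animal, sel$day)),
                                  function(g) {
      if (!nrow(g)) return(NULL)
      cbind(animal = g$animal[1], day = g$day[1], classifyProfile(g))
    }))
    utils::write.csv(prof, file.path(outDir, "profiles.csv"),
                     row.names = FALSE)
    ran <- c(ran, "selectivity")
  }
  matchings <- NULL
  if ("registration" %in% stages || "stability" %in% stages) {
    matchings <- lapply(animals, function(a) matchAcrossDays(cohort, a))
    names(matchings) <- animals
  }
  if ("registration" %in% stages) {
    mt <- do.call(rbind, lapply(animals, function(a) {
      do.call(rbind, lapply(names(matchings[[a]]), function(k) {
        m <- matchings[[a]][[k]]
        if (!nrow(m)) return(NULL)
        dd <- strsplit(k, "-", fixed = TRUE)[[1]]
        data.frame(animal = a, dayI = as.integer(dd[1]),
                   dayJ = as.integer(dd[2]), idI = m$idI, idJ = m$idJ,
                   dist = m$dist, stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(mt, file.path(outDir, "matching.csv"),
                     row.names = FALSE)
    ran <- c(ran, "registration")
  }
  if ("decoding" %in% stages) {
    dec <- do.call(rbind, lapply(sessions(cohort), function(s) {
      tensor <- binActivity(s, task)
      tr <- trialTable(s)
      do.call(rbind, lapply(epochsDecoded, function(e) {
        lab <- if (e == "choice") ifelse(tr$licked, "lick", "nolick")
               else tr$firstOdour
        r <- sameDayDecoding(tensor, lab, windows, decCfg, epochs = e,
                             seed = childSeed(seed,
                                              1000 + dayIndex(s) * 10 +
                                                match(e, EPOCHS)))
        data.frame(animal = animalId(s), day = dayIndex(s),
                   labelSet = if (e == "choice") "choice" else "first_odour",
                   epoch = e, accuracy = epochAccuracy(r, e),
                   se = r@epochAccuracy$se[r@epochAccuracy$epoch == e],
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(dec, file.path(outDir, "decoding_accuracy.csv"),
                     row.names = FALSE)
    ran <- c(ran, "decoding")
  }
  if ("stability" %in% stages) {
    mats <- lapply(animals, function(a)
      crossDayDecoding(cohort, a, "first_odour", task, windows,
                       epoch = "first_odour",
                       config = decodingConfig(nRepeats = decCfg$nRepeats),
                       matching = matchings[[a]],
                       seed = childSeed(seed, 3000 + match(a, animals))))
    cdm <- do.call(rbind, lapply(mats, function(m) {
      ij <- expand.grid(trainDay = m@days, testDay = m@days)
      data.frame(animal = m@animalId, epoch = m@epoch,
                 labelSet = m@labelSet, trainDay = ij$trainDay,
                 testDay = ij$testDay,
                 accuracy = as.vector(t(m@acc))[
                   (match(ij$trainDay, m@days) - 1) * length(m@days) +
                     match(ij$testDay, m@days)],
                 nMatched = as.vector(t(m@nMatched))[
                   (match(ij$trainDay, m@days) - 1) * length(m@days) +
                     match(ij$testDay, m@days)],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(cdm, file.path(outDir, "crossday_matrix.csv"),
                     row.names = FALSE)
    st <- blockStabilityStat(mats, earlyDays, lateDays)
    sh <- dayShuffleTest(mats, earlyDays, lateDays, nPerm = 500,
                         seed = childSeed(seed, 4000))
    avg <- Reduce("+", lapply(mats, slot, "acc")) / length(mats)
    cd <- if (length(days) >= 4) estimateCrystallizationDay(avg)$day
          else NA_integer_
    jsonlite::write_json(
      list(earlyDays = earlyDays, lateDays = lateDays,
           earlyMean = mean(st$earlyMeans), lateMean = mean(st$lateMeans),
           difference = st$difference, t = st$t, p = st$p,
           shuffleP = sh$p, crystallizationDay = cd),
      file.path(outDir, "stability_stats.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    ran <- c(ran, "stability")
  }
  manifest <- list(stages = ran, seed = seed,
                   config = cohort@config[!vapply(cohort@config, is.function,
                                                  logical(1))],
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable summary report of pipeline outputs
#'
#' Assembles markdown tables from the stage CSVs present in an output
#' directory: selective fractions by epoch, decoding accuracy by epoch, and
#' the early/late stability contrast. Missing stages are noted rather than
#' failing.
#'
#' @param outDir pipeline output directory.
#' @return character vector of report lines (also usable via
#'   \code{writeLines}).
#' @export
reportSummary <- function(outDir) {
  lines <- c("# Pipeline summary", "")
  bf <- file.path(outDir, "behaviour.csv")
  if (file.exists(bf)) {
    b <- utils::read.csv(bf)
    lines <- c(lines, "## Behaviour",
               sprintf("- mean performance: %.3f (n = %d sessions)",
                       mean(b$performance), nrow(b)),
               sprintf("- mean d-prime: %.2f", mean(b$dprime, na.rm = TRUE)),
               "")
  } else lines <- c(lines, "## Behaviour", "- (missing)", "")
  sf <- file.path(outDir, "selectivity.csv")
  if (file.exists(sf)) {
    s <- utils::read.csv(sf)
    frac <- tapply(s$selective, s$epoch, mean)
    lines <- c(lines, "## Selective fractions by epoch",
               sprintf("- %s: %.3f", names(frac), frac), "")
  } else lines <- c(lines, "## Selective fractions by epoch", "- (missing)", "")
  df <- file.path(outDir, "decoding_accuracy.csv")
  if (file.exists(df)) {
    d <- utils::read.csv(df)
    accs <- tapply(d$accuracy, d$epoch, mean)
    lines <- c(lines, "## Same-day decoding accuracy by epoch",
               sprintf("- %s: %.3f", names(accs), accs), "")
  } else lines <- c(lines, "## Same-day decoding accuracy by epoch",
                    "- (missing)", "")
  jf <- file.path(outDir, "stability_stats.json")
  if (file.exists(jf)) {
    st <- jsonlite::read_json(jf)
    lines <- c(lines, "## Cross-day stability",
               sprintf("- early-block mean: %.3f", st$earlyMean),
               sprintf("- late-block mean: %.3f", st$lateMean),
               sprintf("- difference: %.3f (t = %.2f, p = %.4g; day-shuffle p = %.4g)",
                       st$difference, st$t, st$p, st$shuffleP),
               sprintf("- estimated crystallization day: %s",
                       st$crystallizationDay %||% "none"), "")
  } else lines <- c(lines, "## Cross-day stability", "- (missing)", "")
  lines
}
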