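## Linear population decoding: per-bin max-margin classifiers with repeated
## stratified 90/10 splits, label-shuffle chance, top-N% curves,
## depth-stratified and correct-vs-error protocols.

#' Decoding protocol configuration
#'
#' @param trainFraction fraction of trials used for training in each repeat
#'   (default 0.9, stratified by label).
#' @param nRepeats number of random-split repeats (default 32).
#' @param cost inverse-regularization strength of the linear max-margin
#'   classifier (fixed C = 1 by default).
#' @param nGrid top-N\% grid for [topFractionCurve].
#' @return list of class \code{DecodingConfig}.
#' @export
decodingConfig <- function(trainFraction = 0.9, nRepeats = 32, cost = 1,
                           nGrid = c(1, 2, 4, 8, 16, 32, 64, 100)) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  if (nRepeats < 1) stop("nRepeats must be >= 1")
  structure(list(trainFraction = trainFraction, nRepeats = nRepeats,
                 cost = cost, nGrid = nGrid), class = "DecodingConfig")
}

#' Per-bin and per-epoch decoding accuracy
#'
#' @slot binAccuracy data.frame (bin, binStart, epoch, accuracy, se).
#' @slot epochAccuracy data.frame (epoch, accuracy, se); the epoch aggregate
#'   is the mean of its member bins' accuracies.
#' @slot nNeurons,nRepeats protocol bookkeeping.
#' @slot labelSet label set decoded.
#' @export
setClass("DecodingResult", representation(
  binAccuracy = "data.frame", epochAccuracy = "data.frame",
  nNeurons = "integer", nRepeats = "integer", labelSet = "character"
))

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s; %d neurons, %d repeats):\n",
              object@labelSet, object@nNeurons, object@nRepeats))
  print(object@epochAccuracy, digits = 3)
})

#' @rdname accessors
#' @param epoch epoch name.
#' @export
epochAccuracy <- function(x, epoch = NULL) {
  ea <- x@epochAccuracy
  if (is.null(epoch)) return(ea)
  ea$accuracy[match(epoch, ea$epoch)]
}

## Standardize features on the training split only, then fit a linear
## max-margin classifier (libsvm, C fixed by config).
fitLinearDecoder <- function(xtr, ytr, cost = 1) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(xtr, 2, mu, "-"), 2, sdv, "/")
  model <- e1071::svm(xs, ytr, kernel = "linear", cost = cost, scale = FALSE)
  list(model = model, mu = mu, sd = sdv)
}

predictDecoder <- function(fit, xte) {
  xs <- sweep(sweep(xte, 2, fit$mu, "-"), 2, fit$sd, "/")
  stats::predict(fit$model, xs)
}

## Stratified train indices: floor(f * n_l) per label, clamped so that every
## label keeps at least one training and one test trial.
stratifiedSplit <- function(y, trainFraction) {
  idx <- integer(0)
  for (l in unique(y)) {
    ii <- which(y == l)
    k <- max(1L, min(length(ii) - 1L, floor(trainFraction * length(ii))))
    idx <- c(idx, sample(ii, k))
  }
  sort(idx)
}

## Map each bin to the epoch whose window contains its start (NA if none).
binEpochs <- function(tensor, windows) {
  vapply(tensor@binStarts, function(t0) {
    for (e in EPOCHS) {
      w <- windows@windows[e, ]
      if (t0 >= w[1] - 1e-9 && t0 < w[2] - 1e-9) return(e)
    }
    NA_character_
  }, character(1))
}

selectBins <- function(tensor, windows, epochs) {
  be <- binEpochs(tensor, windows)
  if (is.null(epochs)) which(!is.na(be)) else which(be %in% epochs)
}

#' Same-day cross-validated population decoding
#'
#' For each 500 ms bin, trains a linear max-margin classifier on a stratified
#' random 90\% of trials and tests it on the held-out 10\%, repeating with
#' fresh splits (default 32 repeats) and averaging. Features are the per-bin
#' population vectors, standardized per neuron on the training split only.
#' Multi-way label sets are handled by one-vs-one voting between binary
#' linear decoders. Epoch accuracy is the mean over the epoch's member bins.
#'
#' @param tensor a [TrialTensor-class].
#' @param labels per-trial labels (2 or more classes; at least 5 trials per
#'   class).
#' @param windows an [EpochWindows-class].
#' @param config a \code{DecodingConfig}.
#' @param epochs restrict decoding to these epochs (NULL = all epochs).
#' @param seed integer master seed; split r uses a child seed derived from
#'   (seed, r).
#' @param neurons optional neuron (column) subset.
#' @return A [DecodingResult-class].
#' @export
sameDayDecoding <- function(tensor, labels, windows,
                            config = decodingConfig(), epochs = NULL,
                            seed = NULL, neurons = NULL) {
  y <- factor(labels)
  if (min(table(y)) < 5) stop("need at least 5 trials per label")
  bins <- selectBins(tensor, windows, epochs)
  if (!length(bins)) stop("no bins to decode")
  v <- tensor@values
  if (!is.null(neurons)) v <- v[, neurons, , drop = FALSE]
  nB <- length(bins)
  acc <- matrix(NA_real_, config$nRepeats, nB)
  for (r in seq_len(config$nRepeats)) {
    tr <- withSeed(if (is.null(seed)) NULL else childSeed(seed, r), {
      attempt <- 0L
      repeat {
        tr <- stratifiedSplit(y, config$trainFraction)
        if (length(unique(y[tr])) == nlevels(y)) break
        attempt <- attempt + 1L
        if (attempt >= 100L) stop("could not build a split containing all labels")
      }
      tr
    })
    te <- setdiff(seq_along(y), tr)
    for (b in seq_len(nB)) {
      x <- v[, , bins[b], drop = FALSE]
      dim(x) <- dim(x)[1:2]
      fit <- fitLinearDecoder(x[tr, , drop = FALSE], y[tr], config$cost)
      pred <- predictDecoder(fit, x[te, , drop = FALSE])
      acc[r, b] <- mean(pred == y[te])
    }
  }
  be <- binEpochs(tensor, windows)[bins]
  binAcc <- data.frame(bin = bins, binStart = tensor@binStarts[bins],
                       epoch = be, accuracy = colMeans(acc),
                       se = apply(acc, 2, stats::sd) / sqrt(config$nRepeats),
                       stringsAsFactors = FALSE)
  epAcc <- do.call(rbind, lapply(unique(be[!is.na(be)]), function(e) {
    sub <- binAcc[binAcc$epoch %in% e, ]
    data.frame(epoch = e, accuracy = mean(sub$accuracy),
               se = mean(sub$se), stringsAsFactors = FALSE)
  }))
  new("DecodingResult", binAccuracy = binAcc, epochAccuracy = epAcc,
      nNeurons = dim(v)[2], nRepeats = as.integer(config$nRepeats),
      labelSet = paste(levels(y), collapse = "/"))
}

#' Label-shuffle chance distribution
#'
#' Reruns [sameDayDecoding] with labels randomly reassigned to trials,
#' yielding the chance accuracy distribution used as the null for all
#' decoding claims.
#'
#' @inheritParams sameDayDecoding
#' @param nShuffles number of label shuffles.
#' @return list with \code{perShuffle} (epoch x shuffle accuracy matrix),
#'   \code{summary} data.frame (epoch, mean, sd, q025, q975).
#' @export
shuffleChance <- function(tensor, labels, windows,
                          config = decodingConfig(), epochs = NULL,
                          nShuffles = 10, seed = NULL) {
  eps <- NULL
  accs <- matrix(NA_real_, 0, 0)
  res <- vector("list", nShuffles)
  for (s in seq_len(nShuffles)) {
    sh <- withSeed(if (is.null(seed)) NULL else childSeed(seed, 7000 + s),
                   sample(labels))
    r <- sameDayDecoding(tensor, sh, windows, config, epochs,
                         seed = if (is.null(seed)) NULL
                                else childSeed(seed, 8000 + s))
    res[[s]] <- r@epochAccuracy
  }
  eps <- res[[1]]$epoch
  accs <- vapply(res, function(d) d$accuracy, numeric(length(eps)))
  accs <- matrix(accs, nrow = length(eps), dimnames = list(eps, NULL))
  summ <- data.frame(
    epoch = eps, mean = rowMeans(accs), sd = apply(accs, 1, stats::sd),
    q025 = apply(accs, 1, stats::quantile, 0.025),
    q975 = apply(accs, 1, stats::quantile, 0.975), stringsAsFactors = FALSE)
  list(perShuffle = accs, summary = summ)
}

#' Decoding accuracy versus top-N\% most selective neurons
#'
#' For each N in the grid, decodes with only the ceil(N\% x nNeurons)
#' top-ranked neurons (ranking supplied by the caller, most selective
#' first).
#'
#' @inheritParams sameDayDecoding
#' @param ranking neuron column indices ordered most to least selective;
#'   must cover all neurons.
#' @param epoch single epoch decoded.
#' @return data.frame (N, nNeurons, flagged, accuracy, se).
#' @export
topFractionCurve <- function(tensor, labels, ranking, windows,
                             config = decodingConfig(), epoch = "first_odour",
                             seed = NULL) {
  nN <- nNeurons(tensor)
  if (length(ranking) != nN || !setequal(ranking, seq_len(nN)))
    stop("ranking must be a permutation of all neuron indices")
  out <- lapply(config$nGrid, function(N) {
    k <- ceiling(N / 100 * nN)
    flagged <- N / 100 * nN < 1
    k <- max(1L, k)
    r <- sameDayDecoding(tensor, labels, windows, config, epochs = epoch,
                         seed = seed, neurons = ranking[seq_len(k)])
    data.frame(N = N, nNeurons = k, flagged = flagged,
               accuracy = epochAccuracy(r, epoch),
               se = r@epochAccuracy$se[r@epochAccuracy$epoch == epoch])
  })
  do.call(rbind, out)
}

#' Depth-stratified decoding
#'
#' Divides the bottom \code{nIntervals x intervalWidth} micrometres of the
#' imaged volume (420 um in seven 60 um intervals by default) into depth
#' intervals, equalizes the neuron count across intervals by random
#' subsampling down to the smallest interval census, and decodes per
#' interval.
#'
#' @inheritParams sameDayDecoding
#' @param depths per-neuron depth (micrometres).
#' @param epoch single epoch decoded.
#' @param nIntervals,intervalWidth stratification geometry.
#' @return list with \code{table} data.frame (interval, depthLo, depthHi,
#'   census, nUsed, accuracy, se) and \code{equalizedCount}.
#' @export
depthStratifiedDecoding <- function(tensor, depths, labels, windows,
                                    config = decodingConfig(),
                                    epoch = "late_delay", nIntervals = 7,
                                    intervalWidth = 60, seed = NULL) {
  if (length(depths) != nNeurons(tensor))
    stop("depths must have one entry per neuron")
  top <- max(depths) - nIntervals * intervalWidth
  lo <- top + (seq_len(nIntervals) - 1) * intervalWidth
  hi <- lo + intervalWidth
  member <- lapply(seq_len(nIntervals), function(i)
    which(depths >= lo[i] & depths < hi[i] + ifelse(i == nIntervals, 1e-9, 0)))
  census <- lengths(member)
  if (any(census == 0))
    stop(sprintf("empty depth interval [%g, %g) um",
                 lo[which(census == 0)[1]], hi[which(census == 0)[1]]))
  m <- min(census)
  rows <- lapply(seq_len(nIntervals), function(i) {
    sel <- withSeed(if (is.null(seed)) NULL else childSeed(seed, 100 + i),
                    sample(member[[i]], m))
    r <- sameDayDecoding(tensor, labels, windows, config, epochs = epoch,
                         seed = if (is.null(seed)) NULL
                                else childSeed(seed, 200 + i),
                         neurons = sel)
    data.frame(interval = i, depthLo = lo[i], depthHi = hi[i],
               census = census[i], nUsed = m,
               accuracy = epochAccuracy(r, epoch),
               se = r@epochAccuracy$se[r@epochAccuracy$epoch == epoch])
  })
  list(table = do.call(rbind, rows), equalizedCount = m)
}

#' Four-way trial-category decoding
#'
#' Discriminates the trial categories AC/AD/BC/BD (one-vs-one voting between
#' linear binary decoders) with the standard protocol; typically applied to
#' the second-odour epoch, where all four categories first become
#' distinguishable.
#'
#' @inheritParams sameDayDecoding
#' @param trialTypes per-trial AC/AD/BC/BD labels.
#' @return A [DecodingResult-class].
#' @export
decodeTrialCategory <- function(tensor, trialTypes, windows,
                                config = decodingConfig(), epochs = NULL,
                                seed = NULL) {
  sameDayDecoding(tensor, trialTypes, windows, config, epochs, seed)
}

#' Train on correct trials, test on error trials
#'
#' Replicates the error-trial dissociation protocol: in each repeat a
#' stratified 90\% of correct trials trains the decoder and all error trials
#' form the test set. Because error trials are few and their label mix is
#' arbitrary, accuracy is balanced (mean of per-class recalls), whose chance
#' level is exactly 1/2 regardless of the error-trial label composition.
#' With \code{nShuffles > 0} a chance band is computed by permuting the
#' training labels.
#'
#' @inheritParams sameDayDecoding
#' @param isError logical per-trial error flag.
#' @param nShuffles label shuffles for the chance band (0 = none).
#' @return list with \code{epochAccuracy} data.frame and (when shuffled)
#'   \code{chance} data.frame (epoch, mean, sd).
#' @export
correctErrorDecoding <- function(tensor, labels, isError, windows,
                                 config = decodingConfig(), epochs = NULL,
                                 seed = NULL, nShuffles = 0) {
  if (sum(isError) < 5) stop("need at least 5 error trials")
  y <- factor(labels)
  corr <- which(!isError); err <- which(isError)
  bins <- selectBins(tensor, windows, epochs)
  be <- binEpochs(tensor, windows)[bins]
  v <- tensor@values
  runOnce <- function(yCorr, sseed) {
    acc <- matrix(NA_real_, config$nRepeats, length(bins))
    for (r in seq_len(config$nRepeats)) {
      tr <- withSeed(if (is.null(sseed)) NULL else childSeed(sseed, r), {
        keep <- stratifiedSplit(yCorr, config$trainFraction)
        list(idx = corr[keep], y = yCorr[keep])
      })
      for (b in seq_along(bins)) {
        x <- v[, , bins[b], drop = FALSE]
        dim(x) <- dim(x)[1:2]
        fit <- fitLinearDecoder(x[tr$idx, , drop = FALSE], tr$y, config$cost)
        pred <- predictDecoder(fit, x[err, , drop = FALSE])
        perClass <- vapply(levels(y), function(l)
          mean(pred[y[err] == l] == l), numeric(1))
        acc[r, b] <- mean(perClass, na.rm = TRUE)
      }
    }
    vapply(unique(be), function(e) mean(acc[, be == e]), numeric(1))
  }
  obs <- runOnce(y[corr], seed)
  out <- list(epochAccuracy = data.frame(epoch = unique(be), accuracy = obs,
                                         stringsAsFactors = FALSE))
  if (nShuffles > 0) {
    ## permute the correct-trial labels once per shuffle, then rerun the
    ## whole repeated protocol, so the null carries the same repeat-to-
    ## repeat coherence as the observed statistic
    ch <- vapply(seq_len(nShuffles), function(s) {
      yPerm <- withSeed(if (is.null(seed)) NULL else childSeed(seed, 5000 + s),
                        sample(y[corr]))
      runOnce(yPerm, if (is.null(seed)) NULL else childSeed(seed, 6000 + s))
    }, numeric(length(unique(be))))
    ch <- matrix(ch, nrow = length(unique(be)))
    out$chance <- data.frame(epoch = unique(be), mean = rowMeans(ch),
                             sd = apply(ch, 1, stats::sd),
                             stringsAsFactors = FALSE)
  }
  out
}
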