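## Cross-session neuron matching from centroid geometry.

#' Match neurons across two sessions by centroid distance
#'
#' Greedy one-to-one matching: all centroid pairs within \code{maxDist}
#' micrometres (10 um by default, the ceiling used for cross-day
#' co-registration) are sorted by ascending distance and accepted whenever
#' both members are still unmatched, which guarantees a one-to-one table and
#' always accepts mutual nearest neighbours first. Distances are 3-D when a
#' depth column is present in both tables, 2-D otherwise.
#'
#' @param centroidsI,centroidsJ data.frames with columns \code{x}, \code{y}
#'   and optionally \code{depth}; rownames or an \code{id} column may carry
#'   neuron identifiers.
#' @param maxDist maximal accepted centroid distance (micrometres).
#' @param idsI,idsJ neuron identifiers (default: row index).
#' @return list with data.frame \code{matches} (idI, idJ, dist, indexI,
#'   indexJ) and character vectors \code{unmatchedI}, \code{unmatchedJ}.
#' @examples
#' a <- data.frame(x = c(0, 50), y = c(0, 0))
#' matchNeurons(a, a)$matches  # identical constellations match at 0 um
#' @export
matchNeurons <- function(centroidsI, centroidsJ, maxDist = 10,
                         idsI = NULL, idsJ = NULL) {
  cols <- intersect(c("x", "y", "depth"),
                    intersect(names(centroidsI), names(centroidsJ)))
  if (!all(c("x", "y") %in% cols))
    stop("centroid tables must share x and y columns")
  A <- as.matrix(centroidsI[, cols, drop = FALSE])
  B <- as.matrix(centroidsJ[, cols, drop = FALSE])
  if (!nrow(A) || !nrow(B)) stop("centroid arrays must be non-empty")
  if (is.null(idsI)) idsI <- rownames(centroidsI) %||% as.character(seq_len(nrow(A)))
  if (is.null(idsJ)) idsJ <- rownames(centroidsJ) %||% as.character(seq_len(nrow(B)))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  cand <- which(dist <= maxDist, arr.ind = TRUE)
  mi <- integer(0); mj <- integer(0); md <- numeric(0)
  if (nrow(cand)) {
    dd <- dist[cand]
    ## deterministic tie-break: distance, then row, then column index
    ord <- order(dd, cand[, 1], cand[, 2])
    usedI <- logical(nrow(A)); usedJ <- logical(nrow(B))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!usedI[i] && !usedJ[j]) {
        usedI[i] <- TRUE; usedJ[j] <- TRUE
        mi <- c(mi, i); mj <- c(mj, j); md <- c(md, dist[i, j])
      }
    }
  }
  list(matches = data.frame(idI = idsI[mi], idJ = idsJ[mj], dist = md,
                            indexI = mi, indexJ = mj,
                            stringsAsFactors = FALSE),
       unmatchedI = idsI[setdiff(seq_len(nrow(A)), mi)],
       unmatchedJ = idsJ[setdiff(seq_len(nrow(B)), mj)])
}

#' Match neurons across all day pairs of one animal
#'
#' @param cohort a [Cohort-class].
#' @param animal animal identifier.
#' @param maxDist maximal centroid distance (micrometres).
#' @return named list (\code{"i-j"}) of [matchNeurons] match data.frames,
#'   for all ordered day pairs i < j.
#' @export
matchAcrossDays <- function(cohort, animal, maxDist = 10) {
  ss <- animalSessions(cohort, animal)
  days <- vapply(ss, dayIndex, integer(1))
  out <- list()
  for (a in seq_along(ss)) for (b in seq_along(ss)) {
    if (a >= b) next
    m <- matchNeurons(centroids(ss[[a]]), centroids(ss[[b]]), maxDist,
                      idsI = neuronIds(ss[[a]]), idsJ = neuronIds(ss[[b]]))
    out[[sprintf("%d-%d", days[a], days[b])]] <- m$matches
  }
  out
}
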