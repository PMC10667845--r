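# Cross-session unit tracking by waveform PCA distance. Two units recorded
# on corresponding channels in adjacent sessions are putatively the same
# neuron when the distance between their waveform PC cluster centers is less
# than 2 sigma of the earlier session's PC score distribution.

#' Project two sessions' waveforms into a shared PC space
#'
#' Fits a PCA basis on the waveform snippets of a session pair (pooled by
#' default, so the distance is symmetric in spirit; \code{fit = "earlier"}
#' fits on session A only) and projects both snippet sets onto the first
#' \code{nComponents} components.
#'
#' @param waveformsA,waveformsB snippet matrices with identical snippet
#'   length (columns).
#' @param nComponents number of retained components.
#' @param fit "pooled" or "earlier".
#' @return list with \code{scoresA}, \code{scoresB} (rows = snippets),
#'   \code{basis} (n_samples x nComponents, orthonormal columns) and
#'   \code{center}.
#' @export
waveformPcScores <- function(waveformsA, waveformsB, nComponents = 2,
                             fit = c("pooled", "earlier")) {
  fit <- match.arg(fit)
  if (ncol(waveformsA) != ncol(waveformsB))
    stop("snippet length mismatch between sessions")
  fitSet <- if (fit == "pooled") rbind(waveformsA, waveformsB) else waveformsA
  pc <- prcomp(fitSet, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$rotation))
  basis <- pc$rotation[, seq_len(k), drop = FALSE]
  ctr <- pc$center
  list(scoresA = sweep(waveformsA, 2, ctr, "-") %*% basis,
       scoresB = sweep(waveformsB, 2, ctr, "-") %*% basis,
       basis = basis, center = ctr)
}

.cloudSigma <- function(scores) {
  # scalar sigma of a PC score cloud: RMS of the per-component SDs
  sqrt(mean(apply(scores, 2, var)))
}

#' Match units across a session pair
#'
#' For each candidate unit pair (same primary channel, or channels within
#' \code{adjacencyRadius} when positions are given; all pairs otherwise) the
#' waveform clouds are projected into a shared PC space and the
#' center-to-center distance is expressed in units of the earlier session's
#' cloud sigma. A pair is matched when that distance is below
#' \code{sigmaMultiple} (2 by default); a greedy one-to-one assignment by
#' smallest distance resolves conflicts, ties broken by lower unit id.
#'
#' @param unitsA,unitsB lists of \linkS4class{SortedUnit} from the earlier
#'   (A) and later (B) session.
#' @param nComponents PCs retained (default 2).
#' @param sigmaMultiple match threshold in sigmas of session A's cloud.
#' @param fit PCA fitting set, "pooled" (default) or "earlier".
#' @param channelPositions optional data.frame(channel_id, x, y) in um.
#' @param adjacencyRadius um, candidate gate when positions are given.
#' @return data.frame with unit_a, unit_b, center_distance_sigma, matched.
#'   Units without waveforms are skipped with a warning.
#' @export
matchUnits <- function(unitsA, unitsB, nComponents = 2, sigmaMultiple = 2.0,
                       fit = "pooled", channelPositions = NULL,
                       adjacencyRadius = 100) {
  hasWf <- function(u) nrow(waveforms(u)) >= 2L
  dropA <- !vapply(unitsA, hasWf, logical(1))
  dropB <- !vapply(unitsB, hasWf, logical(1))
  if (any(dropA) || any(dropB))
    warning("units without waveforms skipped: ",
            paste(c(vapply(unitsA[dropA], unitId, character(1)),
                    vapply(unitsB[dropB], unitId, character(1))),
                  collapse = ", "))
  unitsA <- unitsA[!dropA]; unitsB <- unitsB[!dropB]

  candidate <- function(a, b) {
    ca <- primaryChannel(a); cb <- primaryChannel(b)
    if (is.na(ca) || is.na(cb)) return(TRUE)
    if (ca == cb) return(TRUE)
    if (is.null(channelPositions)) return(TRUE)
    i <- match(ca, channelPositions$channel_id)
    j <- match(cb, channelPositions$channel_id)
    sqrt((channelPositions$x[i] - channelPositions$x[j])^2 +
         (channelPositions$y[i] - channelPositions$y[j])^2) <=
      adjacencyRadius
  }

  rows <- list()
  for (a in unitsA) for (b in unitsB) {
    if (!candidate(a, b)) next
    sc <- waveformPcScores(waveforms(a), waveforms(b), nComponents, fit)
    dist <- sqrt(sum((colMeans(sc$scoresA) - colMeans(sc$scoresB))^2))
    sigA <- .cloudSigma(sc$scoresA)
    ds <- if (sigA > 0) dist / sigA else if (dist == 0) 0 else Inf
    rows[[length(rows) + 1L]] <-
      data.frame(unit_a = unitId(a), unit_b = unitId(b),
                 center_distance_sigma = ds, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(unit_a = character(0), unit_b = character(0),
                      center_distance_sigma = numeric(0),
                      matched = logical(0)))
  res <- do.call(rbind, rows)
  res <- res[order(res$center_distance_sigma, res$unit_a, res$unit_b), ]

  # greedy one-to-one assignment by smallest distance
  res$matched <- FALSE
  usedA <- usedB <- character(0)
  for (i in seq_len(nrow(res))) {
    if (res$center_distance_sigma[i] >= sigmaMultiple) next
    if (res$unit_a[i] %in% usedA || res$unit_b[i] %in% usedB) next
    res$matched[i] <- TRUE
    usedA <- c(usedA, res$unit_a[i])
    usedB <- c(usedB, res$unit_b[i])
  }
  rownames(res) <- NULL
  res
}

#' Chain unit matches across a session sequence
#'
#' Transitively chains one-to-one matches of consecutive session pairs into
#' unit tracks; chains never branch because the upstream matching is
#' one-to-one. When \code{daysPostImplant} is supplied, each chain's span in
#' days is reported.
#'
#' @param matchList list of match data.frames from \code{\link{matchUnits}},
#'   element k linking session k to session k+1.
#' @param daysPostImplant optional integer vector, one day per session.
#' @return data.frame with chain_id, session_index, unit_id (one row per
#'   chain member) plus a "span_days" attribute per chain when days are
#'   given.
#' @export
chainTracks <- function(matchList, daysPostImplant = NULL) {
  nSessions <- length(matchList) + 1L
  chains <- list()   # each: data.frame(session_index, unit_id)
  open <- list()     # chains whose tail is in the previous session
  for (k in seq_along(matchList)) {
    mk <- matchList[[k]]
    mk <- mk[mk$matched, , drop = FALSE]
    nextOpen <- list()
    for (i in seq_len(nrow(mk))) {
      ua <- mk$unit_a[i]; ub <- mk$unit_b[i]
      prev <- Filter(function(ch) ch$session_index[nrow(ch)] == k &&
                       ch$unit_id[nrow(ch)] == ua, open)
      ch <- if (length(prev)) prev[[1]] else
        data.frame(session_index = k, unit_id = ua, stringsAsFactors = FALSE)
      if (length(prev))
        open <- Filter(function(x) !identical(x, prev[[1]]), open)
      ch <- rbind(ch, data.frame(session_index = k + 1L, unit_id = ub,
                                 stringsAsFactors = FALSE))
      nextOpen[[length(nextOpen) + 1L]] <- ch
    }
    chains <- c(chains, open)   # chains that ended before session k+1
    open <- nextOpen
  }
  chains <- c(chains, open)
  if (!length(chains))
    return(data.frame(chain_id = integer(0), session_index = integer(0),
                      unit_id = character(0), span_days = numeric(0)))
  out <- do.call(rbind, lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    span <- if (!is.null(daysPostImplant))
      daysPostImplant[max(ch$session_index)] -
        daysPostImplant[min(ch$session_index)]
    else NA_real_
    cbind(data.frame(chain_id = i), ch, data.frame(span_days = span))
  }))
  rownames(out) <- NULL
  out
}
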