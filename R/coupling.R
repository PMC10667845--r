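# Functional-coupling inference from pairwise cross-correlograms (CCGs).
# Coincidences are binned at 0.4 ms over lags -200..+200 ms; the slow CCG
# structure is estimated by convolving the observed CCG with a partially
# hollow (60%) Gaussian kernel (sigma 10 ms) whose central weight is
# suppressed so the tested bin does not smooth itself; a pair is functionally
# coupled when the peak inside the 10 ms causal (positive-lag) window
# significantly exceeds that baseline AND significantly exceeds the mirrored
# negative-lag peak, giving a directed leader -> follower verdict.

#' Spike-train cross-correlogram
#'
#' Histogram of follower-minus-leader spike-time differences in
#' \code{binMs}-wide bins with centers at k * binMs for |k * binMs| <=
#' \code{maxLagMs} (1001 bins at the defaults, spanning differences up to
#' +/- 200.2 ms). Satisfies the time-reversal identity
#' ccg(A, B)[k] = ccg(B, A)[-k] exactly.
#'
#' @param trainA leader spike times (s), non-empty.
#' @param trainB follower spike times (s), non-empty.
#' @param binMs bin width (ms).
#' @param maxLagMs maximum lag (ms).
#' @return list with lags (bin centers, ms) and counts (integer).
#' @export
ccg <- function(trainA, trainB, binMs = 0.4, maxLagMs = 200) {
  if (!length(trainA) || !length(trainB))
    stop("ccg requires two non-empty spike trains")
  trainA <- sort(trainA); trainB <- sort(trainB)
  half <- round(maxLagMs / binMs)
  L <- (maxLagMs + binMs / 2) / 1000
  lo <- findInterval(trainA - L, trainB)
  hi <- findInterval(trainA + L, trainB)
  nPer <- hi - lo
  aIdx <- rep.int(seq_along(trainA), nPer)
  bIdx <- sequence(nPer) + rep.int(lo, nPer)
  k <- round((trainB[bIdx] - trainA[aIdx]) * 1000 / binMs)
  k <- k[abs(k) <= half]
  list(lags = (-half:half) * binMs,
       counts = tabulate(k + half + 1L, nbins = 2L * half + 1L))
}

#' Partially hollow Gaussian CCG baseline
#'
#' Convolves the CCG counts with a discrete Gaussian kernel (SD
#' \code{sigmaMs}, truncated at +/- 5 SD) whose central weight is multiplied
#' by (1 - \code{hollowFraction}) before renormalizing to sum 1; the
#' convolution uses reflection padding so the baseline is unbiased at the
#' lag edges. A constant CCG is its own baseline; hollowFraction = 0 gives
#' plain Gaussian smoothing.
#'
#' @param counts CCG counts per bin.
#' @param binMs bin width (ms).
#' @param sigmaMs kernel SD (ms).
#' @param hollowFraction fraction of the central weight removed (0.6).
#' @return numeric baseline, same length as counts.
#' @export
hollowGaussianBaseline <- function(counts, binMs = 0.4, sigmaMs = 10,
                                   hollowFraction = 0.6) {
  stopifnot(length(counts) > 0, hollowFraction >= 0, hollowFraction <= 1)
  half <- ceiling(5 * sigmaMs / binMs)
  w <- dnorm((-half:half) * binMs, mean = 0, sd = sigmaMs)
  w[half + 1L] <- w[half + 1L] * (1 - hollowFraction)
  w <- w / sum(w)
  n <- length(counts)
  pad <- min(half, n - 1L)
  padded <- c(rev(counts[seq_len(pad) + 1L]), counts,
              rev(counts[(n - pad):(n - 1L)]))
  if (pad < half)   # short vectors: extend by edge value
    padded <- c(rep(padded[1], half - pad), padded,
                rep(padded[length(padded)], half - pad))
  out <- stats::filter(padded, w, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# one-sided Poisson tail with continuity (mid-p) correction
.poissonTail <- function(k, lambda) {
  ppois(k - 1, lambda, lower.tail = FALSE) - 0.5 * dpois(k, lambda)
}

#' Detect functional coupling in a CCG
#'
#' Finds the peak bin inside the positive causal window (lags in
#' (0, \code{windowMs}]) and computes its one-sided Poisson tail probability
#' (with mid-p continuity correction) against the hollow-Gaussian baseline
#' at that bin, Bonferroni-adjusted for the number of bins searched (the
#' peak is a maximum over the window). The mirrored negative window
#' ([-\code{windowMs}, 0)) is treated identically. The pair is coupled in
#' the leader -> follower direction iff the adjusted positive-peak
#' probability falls below \code{alpha} AND the positive peak significantly
#' exceeds the negative peak in a one-sided conditional binomial comparison
#' of the two counts at \code{alpha} (the causal rule; a symmetric zero-lag
#' common-drive pair fails it).
#'
#' @param x a list with lags and counts as returned by \code{\link{ccg}}.
#' @param baseline baseline from \code{\link{hollowGaussianBaseline}};
#'   computed from the counts when NULL.
#' @param windowMs causal-window width (ms), default 10.
#' @param alpha significance level, default 0.01.
#' @return a \linkS4class{CCGResult}.
#' @export
detectCoupling <- function(x, baseline = NULL, windowMs = 10, alpha = 0.01) {
  lags <- x$lags; counts <- x$counts
  if (is.null(baseline)) baseline <- hollowGaussianBaseline(counts)
  pos <- which(lags > 0 & lags <= windowMs)
  neg <- which(lags >= -windowMs & lags < 0)
  ip <- pos[which.max(counts[pos])]
  im <- neg[which.max(counts[neg])]
  kp <- counts[ip]; km <- counts[im]
  if (baseline[ip] <= 0 || baseline[im] <= 0) {
    warning("baseline non-positive at the window peak; verdict undefined")
    return(new("CCGResult", lags = lags, counts = as.numeric(counts),
               baseline = baseline, peakLag = lags[ip], peakCount = kp,
               pPositive = NA_real_, pNegative = NA_real_, coupled = FALSE,
               direction = "none"))
  }
  pPos <- min(1, length(pos) * .poissonTail(kp, baseline[ip]))
  pNeg <- min(1, length(neg) * .poissonTail(km, baseline[im]))
  pDir <- if (kp + km > 0)
    pbinom(kp - 1, kp + km, 0.5, lower.tail = FALSE) else 1
  isCoupled <- pPos < alpha && pDir < alpha
  new("CCGResult", lags = lags, counts = as.numeric(counts),
      baseline = baseline, peakLag = lags[ip], peakCount = kp,
      pPositive = pPos, pNegative = pNeg, coupled = isCoupled,
      direction = if (isCoupled) "leader->follower" else "none")
}

#' Functional-coupling graph over a unit population
#'
#' Tests every ordered pair of spike trains with at least \code{minSpikes}
#' spikes each; each unordered pair's CCG is computed once and its mirror
#' reused for the reverse direction. Self-pairs are never tested. Returns
#' the directed edges (coupled verdicts) plus the tested-pair table.
#'
#' @param trains named list of spike-time vectors (s).
#' @param alpha significance level per directed test.
#' @param minSpikes minimum spikes per train (default 100).
#' @param binMs,maxLagMs,windowMs CCG and causal-window parameters.
#' @return list (class "couplingGraph") with \code{nodes},
#'   \code{edges} (leader, follower, peak_lag_ms, peak_count,
#'   baseline_at_peak, p_pos, p_neg), and \code{tested} (unit_a, unit_b).
#' @export
couplingGraph <- function(trains, alpha = 0.01, minSpikes = 100,
                          binMs = 0.4, maxLagMs = 200, windowMs = 10) {
  stopifnot(length(trains) >= 2L, !is.null(names(trains)))
  ok <- vapply(trains, length, integer(1)) >= minSpikes
  nodes <- names(trains)
  edges <- list()
  tested <- list()
  ids <- which(ok)
  for (ii in seq_along(ids)) for (jj in seq_along(ids)) {
    if (jj <= ii) next
    i <- ids[ii]; j <- ids[jj]
    cc <- ccg(trains[[i]], trains[[j]], binMs, maxLagMs)
    ccRev <- list(lags = cc$lags, counts = rev(cc$counts))
    for (d in list(list(cc, nodes[i], nodes[j]),
                   list(ccRev, nodes[j], nodes[i]))) {
      res <- detectCoupling(d[[1]], windowMs = windowMs, alpha = alpha)
      if (coupled(res))
        edges[[length(edges) + 1L]] <- data.frame(
          leader = d[[2]], follower = d[[3]], peak_lag_ms = res@peakLag,
          peak_count = res@peakCount,
          baseline_at_peak = res@baseline[match(res@peakLag, res@lags)],
          p_pos = res@pPositive, p_neg = res@pNegative,
          stringsAsFactors = FALSE)
    }
    tested[[length(tested) + 1L]] <-
      data.frame(unit_a = nodes[i], unit_b = nodes[j],
                 stringsAsFactors = FALSE)
  }
  emptyEdges <- data.frame(leader = character(0), follower = character(0),
                           peak_lag_ms = numeric(0), peak_count = numeric(0),
                           baseline_at_peak = numeric(0), p_pos = numeric(0),
                           p_neg = numeric(0), stringsAsFactors = FALSE)
  out <- list(nodes = nodes,
              edges = if (length(edges)) do.call(rbind, edges) else
                emptyEdges,
              tested = if (length(tested)) do.call(rbind, tested) else
                data.frame(unit_a = character(0), unit_b = character(0)))
  class(out) <- c("couplingGraph", "list")
  out
}

#' Coupling probability versus tuning-preference difference
#'
#' Bins the tested pairs by circular difference in preferred orientation
#' (on [0, 90] degrees) and reports, per bin, the proportion of pairs that
#' are functionally coupled (in either direction).
#'
#' @param graph a \code{\link{couplingGraph}} result.
#' @param prefOrientations named numeric vector (deg on [0, 180)) covering
#'   every tested node.
#' @param breaks bin edges on [0, 90] (default 4 bins of 22.5 deg).
#' @return data.frame with bin (factor), n_tested, n_coupled, proportion.
#' @export
couplingVsTuning <- function(graph, prefOrientations,
                             breaks = seq(0, 90, by = 22.5)) {
  tested <- graph$tested
  stopifnot(all(c(tested$unit_a, tested$unit_b) %in%
                  names(prefOrientations)))
  d <- abs(prefOrientations[tested$unit_a] -
             prefOrientations[tested$unit_b]) %% 180
  d <- pmin(d, 180 - d)
  ekey <- unique(with(graph$edges,
                      paste(pmin(leader, follower),
                            pmax(leader, follower))))
  isC <- paste(pmin(tested$unit_a, tested$unit_b),
               pmax(tested$unit_a, tested$unit_b)) %in% ekey
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  nT <- tapply(rep(1L, length(d)), bin, sum, default = 0L)
  nC <- tapply(as.integer(isC), bin, sum, default = 0L)
  data.frame(bin = levels(bin), n_tested = as.integer(nT),
             n_coupled = as.integer(nC),
             proportion = ifelse(nT > 0, nC / nT, 0),
             row.names = NULL)
}
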