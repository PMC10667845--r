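# Post-sorting unit quality metrics and accept/reject gates. Defaults
# reproduce the curation thresholds used for the chronic V1 recordings:
# firing rate > 0.05 Hz, peak SNR > 1.5, <= 2% of spikes with inter-spike
# intervals within 1.6 ms, and (when the sorter supplies them) isolation
# > 0.95 and noise overlap < 0.03; outlier snippets are removed with a
# generalized ESD (Rosner) test before any waveform metric is computed.

#' Mean firing rate
#'
#' @param spikeTimes spike times (s).
#' @param duration session duration (s), > 0.
#' @return rate in Hz (n spikes / duration).
#' @export
firingRate <- function(spikeTimes, duration) {
  stopifnot(duration > 0)
  length(spikeTimes) / duration
}

#' Fraction of refractory-period violations
#'
#' Counts inter-spike intervals shorter than the refractory bound (1.6 ms by
#' default). The denominator is the number of spikes by default ("fraction
#' of spikes with inter-spike intervals within 1.6 ms"); set
#' \code{denominator = "isis"} to divide by the number of intervals instead.
#' Units whose fraction exceeds 2% are discarded by \code{\link{curateUnits}}.
#'
#' @param spikeTimes sorted spike times (s).
#' @param refractory refractory bound (s).
#' @param denominator "spikes" or "isis".
#' @return fraction in [0, 1]; 0 for fewer than two spikes.
#' @export
isiViolationFraction <- function(spikeTimes, refractory = 0.0016,
                                 denominator = c("spikes", "isis")) {
  denominator <- match.arg(denominator)
  n <- length(spikeTimes)
  if (n < 2L) return(0)
  viol <- sum(diff(spikeTimes) < refractory)
  viol / if (denominator == "spikes") n else (n - 1L)
}

#' Peak-to-trough amplitude of a mean waveform
#'
#' @param meanWaveform numeric vector (uV).
#' @return max minus min (uV).
#' @export
peakToTrough <- function(meanWaveform) {
  stopifnot(length(meanWaveform) > 0)
  max(meanWaveform) - min(meanWaveform)
}

#' Waveform signal-to-noise ratio
#'
#' Peak-to-trough amplitude of the mean waveform divided by twice the SD of
#' the snippet residuals about the mean. For a clean template of
#' peak-to-trough A in noise of SD s this converges to A / (2s). Zero
#' residual noise yields \code{Inf} (reported as-is, a sentinel for a
#' noiseless template).
#'
#' @param snippets matrix, n_snippets x n_samples (uV); needs >= 2 rows.
#' @return unitless SNR.
#' @export
waveformSnr <- function(snippets) {
  stopifnot(is.matrix(snippets), nrow(snippets) >= 2L)
  mw <- colMeans(snippets)
  resid <- sweep(snippets, 2, mw, "-")
  s <- sd(as.numeric(resid))
  if (s == 0) return(Inf)
  peakToTrough(mw) / (2 * s)
}

#' Generalized ESD (Rosner) outlier test on scalars
#'
#' Iterative extreme studentized deviate test for up to \code{maxOutliers}
#' outliers: at step i the most extreme remaining value is studentized and
#' removed, and the count of outliers is the largest i whose statistic
#' exceeds Rosner's critical value at the given alpha.
#'
#' @param x numeric vector.
#' @param alpha significance level.
#' @param maxOutliers maximum number of outliers tested.
#' @return integer indices of x flagged as outliers (possibly empty).
#' @export
gesdTest <- function(x, alpha = 0.05, maxOutliers = max(1L,
                     floor(length(x) * 0.1))) {
  n <- length(x)
  stopifnot(n >= 3L, maxOutliers >= 1L, maxOutliers <= n - 2L)
  remaining <- seq_len(n)
  removed <- integer(0)
  R <- lambda <- numeric(maxOutliers)
  for (i in seq_len(maxOutliers)) {
    xr <- x[remaining]
    dev <- abs(xr - mean(xr))
    j <- which.max(dev)
    s <- sd(xr)
    R[i] <- if (s > 0) dev[j] / s else 0
    removed <- c(removed, remaining[j])
    remaining <- remaining[-j]
    ni <- n - i
    p <- 1 - alpha / (2 * (ni + 1))
    t <- qt(p, df = ni - 1)
    lambda[i] <- ni * t / sqrt((ni - 1 + t^2) * (ni + 1))
  }
  nOut <- if (any(R > lambda)) max(which(R > lambda)) else 0L
  removed[seq_len(nOut)]
}

#' GESD outlier removal for waveform snippets
#'
#' Applies \code{\link{gesdTest}} to the per-snippet L2 distance from the
#' mean waveform; flagged snippets are removed before quality metrics are
#' computed. With fewer than 10 snippets the test is skipped with a warning.
#'
#' @param snippets matrix, n_snippets x n_samples.
#' @param alpha significance level.
#' @param maxFraction maximum fraction of snippets that may be flagged.
#' @return integer row indices of outlier snippets (possibly empty).
#' @export
gesdOutliers <- function(snippets, alpha = 0.05, maxFraction = 0.1) {
  if (!is.matrix(snippets) || nrow(snippets) < 10L) {
    warning("fewer than 10 snippets; GESD outlier test skipped")
    return(integer(0))
  }
  mw <- colMeans(snippets)
  d <- sqrt(rowSums(sweep(snippets, 2, mw, "-")^2))
  gesdTest(d, alpha = alpha,
           maxOutliers = max(1L, floor(nrow(snippets) * maxFraction)))
}

#' Default curation thresholds
#'
#' @return list of the curation gate defaults (strict inequalities as in the
#'   text: firing rate > 0.05 Hz, SNR > 1.5, ISI-violation fraction <= 0.02
#'   at 1.6 ms, isolation > 0.95, noise overlap < 0.03).
#' @export
curationDefaults <- function() {
  list(minFiringRate = 0.05, minSnr = 1.5, maxIsiViolation = 0.02,
       refractory = 0.0016, minIsolation = 0.95, maxNoiseOverlap = 0.03,
       gesdAlpha = 0.05, gesdMaxFraction = 0.1,
       isiDenominator = "spikes")
}

#' Curate sorted units
#'
#' Computes the quality report for every unit and applies the accept/reject
#' gates. A unit is accepted iff its firing rate exceeds
#' \code{minFiringRate} (strictly), its SNR exceeds \code{minSnr}, its
#' ISI-violation fraction is at most \code{maxIsiViolation}, and -- when the
#' external sorter metrics are present on the unit -- isolation exceeds
#' \code{minIsolation} and noise overlap is below \code{maxNoiseOverlap}.
#' GESD-flagged outlier snippets are removed before the waveform metrics.
#' Gates that cannot be evaluated (no waveforms, no external metrics) are
#' skipped. Relaxing any threshold never shrinks the accepted set.
#'
#' @param units list of \linkS4class{SortedUnit}.
#' @param duration session duration (s).
#' @param criteria list of thresholds; see \code{\link{curationDefaults}}.
#' @return data.frame with one row per unit: unit_id, firing_rate,
#'   isi_violation_fraction, peak_to_trough, snr, n_outliers_removed,
#'   accepted, reasons (semicolon-joined failed gates).
#' @export
curateUnits <- function(units, duration, criteria = curationDefaults()) {
  cr <- modifyList(curationDefaults(), criteria)
  rows <- lapply(units, function(u) {
    st <- spikeTimes(u)
    fr <- firingRate(st, duration)
    isi <- isiViolationFraction(st, cr$refractory,
                                denominator = cr$isiDenominator)
    wf <- waveforms(u)
    nOut <- 0L
    p2t <- NA_real_
    snr <- NA_real_
    if (nrow(wf) >= 2L) {
      if (nrow(wf) >= 10L) {
        out <- gesdOutliers(wf, cr$gesdAlpha, cr$gesdMaxFraction)
        nOut <- length(out)
        if (nOut) wf <- wf[-out, , drop = FALSE]
      }
      p2t <- peakToTrough(colMeans(wf))
      snr <- waveformSnr(wf)
    }
    reasons <- character(0)
    if (!(fr > cr$minFiringRate)) reasons <- c(reasons, "firing_rate")
    if (!is.na(snr) && !(snr > cr$minSnr)) reasons <- c(reasons, "snr")
    if (!(isi <= cr$maxIsiViolation)) reasons <- c(reasons, "isi_violation")
    if (!is.na(u@isolation) && !(u@isolation > cr$minIsolation))
      reasons <- c(reasons, "isolation")
    if (!is.na(u@noiseOverlap) && !(u@noiseOverlap < cr$maxNoiseOverlap))
      reasons <- c(reasons, "noise_overlap")
    data.frame(unit_id = unitId(u), firing_rate = fr,
               isi_violation_fraction = isi, peak_to_trough = p2t,
               snr = snr, n_outliers_removed = nOut,
               accepted = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.coincidenceCount <- function(a, b, window) {
  if (!length(a) || !length(b)) return(0L)
  lo <- findInterval(a - window, b)
  hi <- findInterval(a + window, b)
  sum(hi > lo)
}

#' Merge duplicate units across adjacent channels
#'
#' Unit pairs whose primary channels lie within the adjacency radius (100 um)
#' and whose spike-time coincidence (within \code{coincidenceWindow})
#' exceeds \code{minOverlapFraction} of the smaller train are considered the
#' same source split by the sorter and are merged: spikes are pooled and
#' coincident duplicates collapsed to the first train's event. Independent
#' trains coincide only at chance level (about 2 * rate * window per spike)
#' and are left alone.
#'
#' @param units list of \linkS4class{SortedUnit}.
#' @param channelPositions data.frame(channel_id, x, y) in um.
#' @param adjacencyRadius um (default 100).
#' @param coincidenceWindow s (default 0.5 ms).
#' @param minOverlapFraction fraction of the smaller train (default 0.5).
#' @return list of merged \linkS4class{SortedUnit}.
#' @export
mergeDuplicateUnits <- function(units, channelPositions,
                                adjacencyRadius = 100,
                                coincidenceWindow = 0.0005,
                                minOverlapFraction = 0.5) {
  chDist <- function(c1, c2) {
    i <- match(c1, channelPositions$channel_id)
    j <- match(c2, channelPositions$channel_id)
    sqrt((channelPositions$x[i] - channelPositions$x[j])^2 +
         (channelPositions$y[i] - channelPositions$y[j])^2)
  }
  repeat {
    merged <- FALSE
    n <- length(units)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        a <- units[[i]]; b <- units[[j]]
        if (is.na(primaryChannel(a)) || is.na(primaryChannel(b))) next
        if (chDist(primaryChannel(a), primaryChannel(b)) > adjacencyRadius)
          next
        ta <- spikeTimes(a); tb <- spikeTimes(b)
        small <- min(length(ta), length(tb))
        if (small == 0L) next
        co <- .coincidenceCount(if (length(ta) <= length(tb)) ta else tb,
                                if (length(ta) <= length(tb)) tb else ta,
                                coincidenceWindow)
        if (co / small > minOverlapFraction) {
          # drop b's spikes that duplicate an a spike, pool the rest
          lo <- findInterval(tb - coincidenceWindow, ta)
          hi <- findInterval(tb + coincidenceWindow, ta)
          pooled <- sort(c(ta, tb[hi <= lo]))
          units[[i]] <- SortedUnit(unitId(a), unique(pooled),
                                   primaryChannel(a), waveforms(a),
                                   a@isolation, a@noiseOverlap)
          units[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  units
}
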