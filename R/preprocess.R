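# Broadband-trace conditioning and threshold spike detection.
#
# All filters are zero-phase (forward-backward Butterworth via
# signal::filtfilt) so that spike peak alignment is never lag-shifted. The
# "standard deviation of the background signal" is estimated robustly as
# 1.4826 * MAD throughout: spikes and artifacts inflate the naive SD, and the
# robust estimator also makes artifact blanking idempotent.

.robustSd <- function(x) mad(x, constant = 1.4826)

# Butterworth design kept at the zero-pole-gain stage (exact analytic
# poles through the band transform and bilinear steps) and split into
# second-order (biquad) sections. Collapsing a high-order design into one
# direct-form polynomial is numerically fragile when the edges sit far from
# Nyquist (e.g. a 0.3 Hz edge at 20 kHz); the cascaded biquads are well
# conditioned and realize the same magnitude response.
.butterSections <- function(order, W, type) {
  T <- 2
  Ww <- 2 / T * tan(pi * W / T)
  pole <- exp(1i * pi * (2 * seq_len(order) + order - 1) / (2 * order))
  if (order %% 2 == 1) pole[(order + 1) / 2] <- -1
  zpg <- signal::Zpg(zero = numeric(0), pole = pole, gain = 1)
  zpg <- signal::sftrans(zpg, W = Ww, stop = type %in% c("stop", "high"))
  zpg <- signal::bilinear(zpg, T = T)

  pairUp <- function(r) {
    out <- list()
    while (length(r)) {
      if (abs(Im(r[1])) > 1e-9) {
        j <- which.min(abs(r - Conj(r[1])))
        out[[length(out) + 1L]] <- c(r[1], r[j])
        r <- r[-c(1L, j)]
      } else if (length(r) > 1L && any(abs(Im(r[-1])) <= 1e-9)) {
        j <- which(abs(Im(r[-1])) <= 1e-9)[1] + 1L
        out[[length(out) + 1L]] <- c(r[1], r[j])
        r <- r[-c(1L, j)]
      } else {
        out[[length(out) + 1L]] <- r[1]
        r <- r[-1L]
      }
    }
    out
  }
  toPoly <- function(cf)
    Re(c(1, -sum(cf), if (length(cf) == 2) prod(cf) else NULL))
  zs <- pairUp(zpg$zero)
  ps <- pairUp(zpg$pole)
  sections <- lapply(seq_len(max(length(zs), length(ps))), function(k) {
    list(b = if (k <= length(zs)) toPoly(zs[[k]]) else 1,
         a = if (k <= length(ps)) toPoly(ps[[k]]) else 1)
  })
  sections[[1]]$b <- sections[[1]]$b * Re(zpg$gain)
  sections
}

# forward-backward filtering, biquad by biquad, with odd-reflection end
# padding sized to ~3 time constants of the slowest pole so that start-up
# transients decay inside the pads; when the transient outlasts the record
# the padding is skipped (it would only reflect the transient back in)
.zeroPhase <- function(sections, x, samplingRate) {
  n <- length(x)
  maxMod <- max(vapply(sections, function(s) {
    if (length(s$a) < 2L) return(0)
    max(Mod(polyroot(rev(s$a))))
  }, numeric(1)))
  p <- if (maxMod >= 1 || maxMod <= 0) 0L else
    ceiling(-3 / log(maxMod))
  if (p >= n) p <- 0L
  padded <- if (p >= 1L)
    c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  else x
  for (sec in sections)
    padded <- signal::filtfilt(signal::Arma(b = sec$b, a = sec$a), padded)
  as.numeric(padded[(p + 1L):(p + n)])
}

.checkEdges <- function(edges, samplingRate) {
  nyq <- samplingRate / 2
  if (any(edges <= 0) || any(edges >= nyq) || (length(edges) == 2 &&
      edges[1] >= edges[2]))
    stop("filter edges must satisfy 0 < low < high < sampling_rate/2")
}

#' Notch filter for mains interference
#'
#' Zero-phase second-order Butterworth band-stop around the mains frequency
#' (50 Hz by default), used before threshold crossing in the closed-loop
#' feature chain.
#'
#' @param trace numeric voltage vector (uV).
#' @param samplingRate Hz.
#' @param freq notch center (Hz); must be below Nyquist.
#' @param width half-width of the stop band (Hz).
#' @return filtered trace.
#' @export
notchFilter <- function(trace, samplingRate, freq = 50, width = 2) {
  nyq <- samplingRate / 2
  if (freq >= nyq) stop("notch frequency must be below Nyquist")
  # geometrically symmetric edges put the band-stop's transmission zero
  # exactly at the notch frequency
  hi <- freq + width
  lo <- freq^2 / hi
  .zeroPhase(.butterSections(2, c(lo, hi) / nyq, "stop"), trace,
             samplingRate)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward Butterworth filtering of a voltage trace. Covers the
#' spike bands used at sorting time (500-5000 Hz or 250-7500 Hz depending on
#' the recording), the closed-loop feature band (>300 Hz high-pass: pass
#' \code{low = 300, high = NULL}) and LFP extraction (0.3-300 Hz low band).
#' A band-pass is realized as a cascade of a high-pass and a low-pass of the
#' stated order: with widely separated edges (such as the 0.3-300 Hz LFP
#' band) this is numerically stable where a directly designed high-order
#' band-pass is not, and the magnitude response is equivalent away from the
#' edges.
#'
#' @param trace numeric voltage vector (uV).
#' @param samplingRate Hz.
#' @param low,high band edges (Hz); set \code{high = NULL} for a pure
#'   high-pass, \code{low = NULL} for a pure low-pass.
#' @param order Butterworth order (applied once per direction).
#' @return filtered trace.
#' @export
bandpassFilter <- function(trace, samplingRate, low, high, order = 4) {
  nyq <- samplingRate / 2
  .checkEdges(c(low, high), samplingRate)
  out <- trace
  if (!is.null(low))
    out <- .zeroPhase(.butterSections(order, low / nyq, "high"), out,
                      samplingRate)
  if (!is.null(high))
    out <- .zeroPhase(.butterSections(order, high / nyq, "low"), out,
                      samplingRate)
  out
}

#' Common median reference
#'
#' Subtracts the per-sample median across channels from every channel,
#' removing common-mode noise such as motion artifacts. With a single
#' channel the input is returned unchanged with a warning.
#'
#' @param traces numeric matrix, channels x samples.
#' @return referenced matrix of the same shape.
#' @export
commonMedianReference <- function(traces) {
  stopifnot(is.matrix(traces))
  if (nrow(traces) < 2L) {
    warning("common median reference needs >= 2 channels; returning input")
    return(traces)
  }
  med <- apply(traces, 2, median)
  sweep(traces, 2, med, "-")
}

#' Blank high-voltage artifact chunks
#'
#' Replaces 0.1 s chunks of data whose amplitude leaves the range of
#' \code{sdMultiple} standard deviations (robust estimate) with zeros, and
#' reports the blanked intervals. The trace is partitioned into consecutive
#' windows of \code{window} seconds; any window containing an excursion is
#' zeroed wholesale. For a clean Gaussian trace the expected number of false
#' exceedances is about 2N * pnorm(-6), i.e. ~2e-4 per 100k samples at the
#' default threshold.
#'
#' @param trace numeric voltage vector (uV).
#' @param samplingRate Hz.
#' @param sdMultiple threshold in robust SDs (default 6).
#' @param window chunk length in seconds (default 0.1).
#' @return list with \code{trace} (blanked) and \code{intervals}
#'   (data.frame(start, end) in seconds; zero rows when nothing was blanked).
#' @export
removeArtifacts <- function(trace, samplingRate, sdMultiple = 6,
                            window = 0.1) {
  stopifnot(window > 0)
  n <- length(trace)
  s <- .robustSd(trace)
  out <- trace
  if (s == 0 || n == 0L)
    return(list(trace = out,
                intervals = data.frame(start = numeric(0),
                                       end = numeric(0))))
  winN <- max(1L, round(window * samplingRate))
  bad <- which(abs(trace) > sdMultiple * s)
  chunks <- sort(unique((bad - 1L) %/% winN))
  iv <- lapply(chunks, function(cc) {
    lo <- cc * winN + 1L
    hi <- min(n, (cc + 1L) * winN)
    out[lo:hi] <<- 0
    c((lo - 1L) / samplingRate, hi / samplingRate)
  })
  intervals <- if (length(iv))
    as.data.frame(do.call(rbind, iv)) else
    data.frame(numeric(0), numeric(0))
  names(intervals) <- c("start", "end")
  list(trace = out, intervals = intervals)
}

#' Threshold-crossing spike detection
#'
#' Detects spike events on a band-passed trace, either at a multiple of the
#' robust background SD in both polarities (sorting-style, default 4.5 SD)
#' or at an absolute voltage (closed-loop style, e.g. -70 uV). Candidate
#' events are the extremum of each suprathreshold excursion; events closer
#' than one snippet length (1.6 ms) are merged to the larger-amplitude
#' extremum, and each event is aligned to its peak/trough sample.
#'
#' @param trace numeric filtered trace (uV).
#' @param samplingRate Hz.
#' @param mode "sd" (threshold in robust SDs) or "absolute" (threshold in
#'   uV; sign selects the polarity).
#' @param threshold threshold value; must be > 0 in sd mode.
#' @param polarity "both", "neg" or "pos" (sd mode only; absolute mode uses
#'   the sign of \code{threshold}).
#' @param deadTime minimum event separation in seconds (default 1.6 ms, one
#'   snippet length).
#' @return numeric vector of event times (s), aligned to the extremum.
#' @export
detectSpikes <- function(trace, samplingRate, mode = c("sd", "absolute"),
                         threshold = 4.5, polarity = c("both", "neg", "pos"),
                         deadTime = 0.0016) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  n <- length(trace)
  if (mode == "sd") {
    if (threshold <= 0) stop("threshold must be > 0 in sd mode")
    # center on the median so DC offsets never shift the detection count
    trace <- trace - median(trace)
    thr <- threshold * .robustSd(trace)
    if (thr == 0) return(numeric(0))
    over <- switch(polarity,
                   both = abs(trace) > thr,
                   neg = trace < -thr,
                   pos = trace > thr)
  } else {
    over <- if (threshold < 0) trace < threshold else trace > threshold
  }
  idx <- which(over)
  if (!length(idx)) return(numeric(0))

  # contiguous suprathreshold runs -> one candidate at the run extremum
  runStart <- c(TRUE, diff(idx) > 1L)
  runId <- cumsum(runStart)
  cand <- vapply(split(idx, runId), function(ii)
    ii[which.max(abs(trace[ii]))], numeric(1))
  cand <- sort(unname(cand))

  # merge events closer than the dead time, keeping the larger extremum
  deadN <- round(deadTime * samplingRate)
  keep <- logical(length(cand))
  cur <- 1L
  for (i in seq_along(cand)[-1]) {
    if (cand[i] - cand[cur] < deadN) {
      if (abs(trace[cand[i]]) > abs(trace[cand[cur]])) cur <- i
    } else {
      keep[cur] <- TRUE
      cur <- i
    }
  }
  keep[cur] <- TRUE
  (cand[keep] - 1L) / samplingRate
}

#' Extract waveform snippets around detected events
#'
#' Cuts \code{pre} + \code{post} windows (0.4 ms before to 1.2 ms after the
#' peak, by default) around each event; snippet length is
#' \code{round((pre + post) * samplingRate)} samples (32 at 20 kHz). Events
#' too close to the trace edges are dropped and reported.
#'
#' @param trace numeric trace (uV).
#' @param samplingRate Hz.
#' @param times event times (s), peak-aligned.
#' @param pre,post window margins before/after the peak (s).
#' @return list with \code{snippets} (n_kept x n_samples matrix),
#'   \code{times} (kept event times) and \code{dropped} (times discarded at
#'   the edges).
#' @export
extractWaveforms <- function(trace, samplingRate, times, pre = 0.0004,
                             post = 0.0012) {
  preN <- round(pre * samplingRate)
  postN <- round(post * samplingRate)
  len <- preN + postN
  centers <- round(times * samplingRate) + 1L
  ok <- centers - preN >= 1L & centers + postN - 1L <= length(trace)
  snippets <- matrix(NA_real_, nrow = sum(ok), ncol = len)
  kept <- centers[ok]
  for (i in seq_along(kept))
    snippets[i, ] <- trace[(kept[i] - preN):(kept[i] + postN - 1L)]
  list(snippets = snippets, times = times[ok], dropped = times[!ok])
}

#' Bin spike counts
#'
#' Counts spikes in consecutive bins of \code{bin} seconds covering
#' [0, duration); the counts always sum to the number of in-range spikes.
#'
#' @param spikeTimes spike times (s).
#' @param bin bin width (s), > 0.
#' @param duration total duration covered (s); defaults to the last spike.
#' @return integer vector of counts.
#' @export
binnedSpikeCounts <- function(spikeTimes, bin, duration = NULL) {
  stopifnot(bin > 0)
  if (is.null(duration))
    duration <- if (length(spikeTimes)) max(spikeTimes) + 1e-9 else bin
  nb <- max(1L, ceiling(duration / bin))
  idx <- floor(spikeTimes / bin) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}
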