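#' @import methods
#' @importFrom stats sd median mad var dnorm pnorm dpois ppois rpois rexp rnorm
#'   runif qt pt p.adjust wilcox.test prcomp coef predict quantile aggregate
#'   rbinom pbinom setNames residuals
#' @importFrom utils read.csv modifyList head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Sorted single unit
#'
#' Container for one sorted unit: spike times, per-spike waveform snippets on
#' the unit's primary channel, and optional externally supplied sorter metrics
#' (isolation, noise overlap) that curation can gate on when present.
#'
#' @slot unitId character scalar, unique within a session.
#' @slot spikeTimes numeric, spike times in seconds, strictly increasing.
#' @slot primaryChannel integer channel id carrying the largest waveform.
#' @slot waveforms numeric matrix (n_spikes x n_samples, microvolts) of
#'   snippets on the primary channel; may have zero rows when snippets were
#'   not kept.
#' @slot isolation numeric, sorter-reported isolation (NA when absent).
#' @slot noiseOverlap numeric, sorter-reported noise overlap (NA when absent).
#'
#' @export
setClass("SortedUnit",
  representation(
    unitId = "character",
    spikeTimes = "numeric",
    primaryChannel = "integer",
    waveforms = "matrix",
    isolation = "numeric",
    noiseOverlap = "numeric"
  ),
  prototype(
    unitId = NA_character_,
    spikeTimes = numeric(0),
    primaryChannel = NA_integer_,
    waveforms = matrix(numeric(0), nrow = 0, ncol = 0),
    isolation = NA_real_,
    noiseOverlap = NA_real_
  )
)

setValidity("SortedUnit", function(object) {
  msg <- character(0)
  if (length(object@unitId) != 1L || is.na(object@unitId))
    msg <- c(msg, "unitId must be a single non-NA string")
  st <- object@spikeTimes
  if (length(st) && any(!is.finite(st)))
    msg <- c(msg, "spike times must be finite")
  if (length(st) > 1L && any(diff(st) <= 0))
    msg <- c(msg, "spike times must be strictly increasing")
  if (length(st) && any(st < 0))
    msg <- c(msg, "spike times must be non-negative")
  if (nrow(object@waveforms) > 0L &&
      nrow(object@waveforms) != length(st))
    msg <- c(msg, "waveforms must have one row per spike (or zero rows)")
  if (length(msg)) msg else TRUE
})

#' Construct a SortedUnit
#'
#' @param unitId unit identifier (string).
#' @param spikeTimes spike times in seconds, strictly increasing.
#' @param primaryChannel channel id of the unit's largest waveform.
#' @param waveforms optional snippet matrix (n_spikes x n_samples, uV).
#' @param isolation,noiseOverlap optional external sorter metrics.
#' @return A \linkS4class{SortedUnit}.
#' @examples
#' u <- SortedUnit("u1", c(0.1, 0.5, 1.2), 3L)
#' nSpikes(u)
#' @export
SortedUnit <- function(unitId, spikeTimes, primaryChannel = NA_integer_,
                       waveforms = NULL, isolation = NA_real_,
                       noiseOverlap = NA_real_) {
  if (is.null(waveforms))
    waveforms <- matrix(numeric(0), nrow = 0, ncol = 0)
  new("SortedUnit",
      unitId = as.character(unitId),
      spikeTimes = as.numeric(spikeTimes),
      primaryChannel = as.integer(primaryChannel),
      waveforms = waveforms,
      isolation = as.numeric(isolation),
      noiseOverlap = as.numeric(noiseOverlap))
}

#' Recording session container
#'
#' One chronic-recording session: probe geometry, broadband sampling rate,
#' optional raw traces, the trial/event table and the sorted units. All
#' invariants (positive sampling rate, unique channel ids, spike times inside
#' the session, well-formed trials) are enforced by the validity method.
#'
#' The trial table is a data.frame with columns \code{trial_id}, \code{onset},
#' \code{offset} (seconds), \code{condition_type} (one of \code{"orientation"},
#' \code{"grid"}, \code{"direction"}), \code{condition} (degrees; orientation
#' on [0, 180), direction one of the 8 values at 45 degree spacing),
#' \code{grid_x}, \code{grid_y} (stimulus location in visual degrees, fixation
#' at the origin; NA unless condition_type is "grid") and
#' \code{movement_onset} (seconds, NA for non-movement trials).
#'
#' @slot sessionId character scalar.
#' @slot samplingRate broadband sampling rate in Hz (e.g. 20000 or 30000).
#' @slot duration session duration in seconds.
#' @slot channels data.frame with columns channel_id, shank_id, depth (um
#'   below the pia), x, y (um on the shank face).
#' @slot raw optional numeric matrix (channels x samples, uV) or NULL.
#' @slot trials trial table (see Details).
#' @slot units list of \linkS4class{SortedUnit}.
#' @slot dayPostImplant integer days since implantation.
#'
#' @export
setClass("RecordingSession",
  representation(
    sessionId = "character",
    samplingRate = "numeric",
    duration = "numeric",
    channels = "data.frame",
    raw = "matrixOrNULL",
    trials = "data.frame",
    units = "list",
    dayPostImplant = "integer"
  ),
  prototype(
    sessionId = NA_character_,
    samplingRate = 20000,
    duration = 0,
    channels = data.frame(channel_id = integer(0), shank_id = character(0),
                          depth = numeric(0), x = numeric(0), y = numeric(0)),
    raw = NULL,
    trials = NULL,   # replaced in constructor
    units = list(),
    dayPostImplant = NA_integer_
  )
)

#' Empty trial table with the canonical column set
#' @return zero-row data.frame with the session trial-table columns.
#' @export
emptyTrials <- function() {
  data.frame(trial_id = integer(0), onset = numeric(0), offset = numeric(0),
             condition_type = character(0), condition = numeric(0),
             grid_x = numeric(0), grid_y = numeric(0),
             movement_onset = numeric(0), stringsAsFactors = FALSE)
}

.trialCols <- c("trial_id", "onset", "offset", "condition_type", "condition",
                "grid_x", "grid_y", "movement_onset")
.directionGrid <- seq(0, 315, by = 45)

setValidity("RecordingSession", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "sampling_rate must be a single positive number")
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration < 0)
    msg <- c(msg, "duration must be a single non-negative number")
  ch <- object@channels
  if (!all(c("channel_id", "shank_id", "depth", "x", "y") %in% names(ch)))
    msg <- c(msg, "channels must have columns channel_id, shank_id, depth, x, y")
  else {
    if (anyDuplicated(ch$channel_id))
      msg <- c(msg, "channel ids must be unique")
    if (nrow(ch) && any(ch$depth < 0, na.rm = TRUE))
      msg <- c(msg, "channel depth must be >= 0")
  }
  tr <- object@trials
  if (!all(.trialCols %in% names(tr)))
    msg <- c(msg, paste("trials must have columns:",
                        paste(.trialCols, collapse = ", ")))
  else if (nrow(tr)) {
    if (any(tr$onset >= tr$offset))
      msg <- c(msg, "trial onset must precede offset")
    ori <- tr$condition[tr$condition_type == "orientation"]
    if (length(ori) && any(ori < 0 | ori >= 180))
      msg <- c(msg, "orientation must lie in [0, 180)")
    dir <- tr$condition[tr$condition_type == "direction"]
    if (length(dir) && !all(dir %in% .directionGrid))
      msg <- c(msg, "direction must be one of 8 values at 45 degree spacing")
  }
  for (u in object@units) {
    if (!is(u, "SortedUnit")) {
      msg <- c(msg, "units must be SortedUnit objects")
      break
    }
    st <- u@spikeTimes
    if (length(st) && (min(st) < 0 || max(st) > object@duration)) {
      msg <- c(msg, sprintf("unit %s has spike times outside [0, duration]",
                            u@unitId))
    }
    nsamp <- ncol(u@waveforms)
    if (nrow(u@waveforms) > 0L &&
        nsamp != round(0.0016 * object@samplingRate)) {
      msg <- c(msg, sprintf(
        "unit %s snippet length %d != round(1.6 ms x sampling rate) = %d",
        u@unitId, nsamp, round(0.0016 * object@samplingRate)))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RecordingSession
#'
#' @param sessionId session identifier.
#' @param samplingRate broadband sampling rate in Hz.
#' @param duration session duration in seconds.
#' @param channels channel-geometry data.frame (channel_id, shank_id, depth,
#'   x, y); defaults to an empty table.
#' @param raw optional channels x samples matrix of broadband voltage (uV).
#' @param trials trial table; defaults to \code{emptyTrials()}.
#' @param units list of \linkS4class{SortedUnit}.
#' @param dayPostImplant integer days since implantation.
#' @return A validated \linkS4class{RecordingSession}.
#' @examples
#' s <- RecordingSession("s1", samplingRate = 20000, duration = 10)
#' sessionDuration(s)
#' @export
RecordingSession <- function(sessionId, samplingRate = 20000, duration = 0,
                             channels = NULL, raw = NULL, trials = NULL,
                             units = list(), dayPostImplant = NA_integer_) {
  if (is.null(channels))
    channels <- data.frame(channel_id = integer(0), shank_id = character(0),
                           depth = numeric(0), x = numeric(0), y = numeric(0))
  if (is.null(trials)) trials <- emptyTrials()
  new("RecordingSession",
      sessionId = as.character(sessionId),
      samplingRate = as.numeric(samplingRate),
      duration = as.numeric(duration),
      channels = channels, raw = raw, trials = trials,
      units = units, dayPostImplant = as.integer(dayPostImplant))
}

#' Center-out cursor trial
#'
#' A single center-out trial: the timestamped 2D cursor path, the target
#' geometry, the control mode and the outcome. Targets sit on a ring around
#' the center start position; the trial succeeds when the cursor center
#' enters the target disk before the timeout.
#'
#' @slot times sample timestamps in seconds, strictly increasing.
#' @slot positions n x 2 matrix of cursor positions in cm.
#' @slot targetDirection target direction in degrees (one of 8 at 45 deg).
#' @slot targetDistance ring radius in cm (7.5 cm by default geometry).
#' @slot targetRadius target disk radius in cm (1.85 cm = 3.7 cm diameter).
#' @slot mode "hand" or "brain" control.
#' @slot success logical trial outcome.
#' @slot timeout allowed trial duration in seconds.
#'
#' @export
setClass("CursorTrial",
  representation(
    times = "numeric",
    positions = "matrix",
    targetDirection = "numeric",
    targetDistance = "numeric",
    targetRadius = "numeric",
    mode = "character",
    success = "logical",
    timeout = "numeric"
  )
)

setValidity("CursorTrial", function(object) {
  msg <- character(0)
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@positions) != length(object@times))
    msg <- c(msg, "positions must have one row per time sample")
  if (ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be an n x 2 matrix")
  if (length(object@positions) && any(!is.finite(object@positions)))
    msg <- c(msg, "positions must be finite")
  if (!object@mode %in% c("hand", "brain"))
    msg <- c(msg, "mode must be 'hand' or 'brain'")
  if (length(msg)) msg else TRUE
})

#' Construct a CursorTrial
#'
#' @param times sample timestamps (s), strictly increasing.
#' @param positions n x 2 cursor positions (cm).
#' @param targetDirection target direction (deg).
#' @param targetDistance center-to-target distance (cm).
#' @param targetRadius target disk radius (cm).
#' @param mode "hand" or "brain".
#' @param success logical outcome.
#' @param timeout trial timeout (s).
#' @return A \linkS4class{CursorTrial}.
#' @export
CursorTrial <- function(times, positions, targetDirection,
                        targetDistance = 7.5, targetRadius = 1.85,
                        mode = "hand", success = NA, timeout = 10) {
  new("CursorTrial", times = as.numeric(times),
      positions = matrix(as.numeric(positions), ncol = 2),
      targetDirection = as.numeric(targetDirection),
      targetDistance = as.numeric(targetDistance),
      targetRadius = as.numeric(targetRadius),
      mode = mode, success = as.logical(success),
      timeout = as.numeric(timeout))
}

#' Cross-correlogram coupling result
#'
#' Lag-binned coincidence counts between a leader and a follower spike train,
#' the smoothed (partially hollow Gaussian) baseline, the causal-window peak
#' statistics and the coupling verdict.
#'
#' @slot lags bin centers in ms (0.4 ms bins spanning -200..200 ms, 1001 bins).
#' @slot counts integer coincidence counts per lag bin (follower relative to
#'   leader).
#' @slot baseline expected counts per bin after hollow-Gaussian smoothing.
#' @slot peakLag lag (ms) of the peak bin inside the positive causal window.
#' @slot peakCount count at that peak bin.
#' @slot pPositive one-sided significance of the positive-window peak against
#'   the baseline (adjusted for the number of bins searched).
#' @slot pNegative same for the mirrored negative window.
#' @slot coupled logical verdict.
#' @slot direction "leader->follower" when coupled, otherwise "none".
#'
#' @export
setClass("CCGResult",
  representation(
    lags = "numeric",
    counts = "numeric",
    baseline = "numeric",
    peakLag = "numeric",
    peakCount = "numeric",
    pPositive = "numeric",
    pNegative = "numeric",
    coupled = "logical",
    direction = "character"
  )
)

setValidity("CCGResult", function(object) {
  msg <- character(0)
  n <- length(object@lags)
  if (length(object@counts) != n || length(object@baseline) != n)
    msg <- c(msg, "lags, counts and baseline must have equal length")
  if (length(object@counts) && any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})
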