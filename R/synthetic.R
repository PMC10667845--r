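# Synthetic sessions with known ground truth. Every downstream stage
# (preprocessing, curation, tracking, tuning, coupling, task metrics) has a
# parameter-recovery test built on these generators. All generators are pure
# functions of (parameters, seed): they save and restore the global RNG
# state, and per-unit substreams are derived as seed + unit index so adding
# units never perturbs existing ones.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# homogeneous Poisson spikes on piecewise-constant rate segments
.poissonPiecewise <- function(segments) {
  out <- lapply(seq_len(nrow(segments)), function(i) {
    len <- segments$end[i] - segments$start[i]
    lam <- segments$rate[i] * len
    if (lam <= 0) return(numeric(0))
    n <- rpois(1L, lam)
    segments$start[i] + sort(runif(n, 0, len))
  })
  sort(unlist(out))
}

.vonMisesRate <- function(theta, prefDeg, baseline, amplitude, kappa) {
  baseline + amplitude *
    exp(kappa * (cos(2 * (theta - prefDeg) * pi / 180) - 1))
}

.trialTimeline <- function(nTrials, trialDur, gap) {
  onset <- gap + (seq_len(nTrials) - 1L) * (trialDur + gap)
  data.frame(onset = onset, offset = onset + trialDur)
}

#' Simulate an orientation-tuning session
#'
#' Each synthetic unit is a homogeneous Poisson process within each grating
#' trial, with rate \eqn{\lambda(\theta) = b + a\,e^{\kappa(\cos 2(\theta -
#' \theta_p) - 1)}} (a von Mises profile on the doubled angle, so the curve
#' is 180-degree periodic like real orientation tuning), and fires at the
#' baseline rate \eqn{b} between trials. Trial order is randomized by the
#' seed.
#'
#' @param nUnits number of units.
#' @param orientations grating orientations in degrees on [0, 180).
#' @param nTrialsPerOrientation trials per orientation.
#' @param trialDur stimulus duration (s).
#' @param gap inter-trial interval (s).
#' @param params list with \code{baseline} (Hz), \code{amplitude} (Hz),
#'   \code{kappa} (concentration, unitless) and optional
#'   \code{prefOrientation} (deg; default draws one per unit).
#' @param seed integer root seed.
#' @return list with \code{session} (a \linkS4class{RecordingSession}) and
#'   \code{truth} (per-unit data.frame of generative parameters).
#' @examples
#' g <- genOrientationSession(nUnits = 2, nTrialsPerOrientation = 3, seed = 1)
#' g$truth
#' @export
genOrientationSession <- function(nUnits = 8,
                                  orientations = seq(0, 157.5, by = 22.5),
                                  nTrialsPerOrientation = 10,
                                  trialDur = 1, gap = 0.5,
                                  params = list(baseline = 2, amplitude = 18,
                                                kappa = 2),
                                  seed = 1) {
  stopifnot(length(orientations) > 0, trialDur > 0)
  b <- params$baseline; a <- params$amplitude; k <- params$kappa
  nTrials <- length(orientations) * nTrialsPerOrientation
  tl <- .trialTimeline(nTrials, trialDur, gap)
  duration <- max(tl$offset) + gap

  condSeq <- .withSeed(seed,
    sample(rep(orientations, each = nTrialsPerOrientation)))
  prefs <- if (!is.null(params$prefOrientation))
    rep_len(params$prefOrientation, nUnits)
  else .withSeed(seed + 20000L, runif(nUnits, 0, 180))

  trials <- data.frame(trial_id = seq_len(nTrials), onset = tl$onset,
                       offset = tl$offset, condition_type = "orientation",
                       condition = condSeq, grid_x = NA_real_,
                       grid_y = NA_real_, movement_onset = NA_real_,
                       stringsAsFactors = FALSE)

  unitsList <- lapply(seq_len(nUnits), function(i) {
    rates <- .vonMisesRate(condSeq, prefs[i], b, a, k)
    seg <- rbind(
      data.frame(start = c(0, tl$offset),
                 end = c(tl$onset, duration), rate = b),
      data.frame(start = tl$onset, end = tl$offset, rate = rates))
    st <- .withSeed(seed + i, .poissonPiecewise(seg))
    SortedUnit(sprintf("u%02d", i), unique(st), i)
  })

  session <- RecordingSession(sprintf("ori-seed%d", seed),
                              samplingRate = 20000, duration = duration,
                              trials = trials, units = unitsList)
  truth <- data.frame(unit_id = vapply(unitsList, unitId, character(1)),
                      pref_orientation = prefs, baseline = b, amplitude = a,
                      kappa = k, stringsAsFactors = FALSE)
  list(session = session, truth = truth, seed = seed)
}

#' Simulate a center-out direction-tuning session
#'
#' Units fire at baseline \eqn{b} throughout and at the rectified-cosine rate
#' \eqn{\lambda(d) = b + m\,\max(0, \cos(d - d_p))} inside the movement epoch
#' (0 to \code{epoch} s after movement onset), emulating cosine-tuned motor
#' units. Eight target directions at 45-degree spacing.
#'
#' @param nUnits number of units.
#' @param nTrialsPerDirection trials per direction.
#' @param trialDur,gap trial duration and inter-trial gap (s).
#' @param moveDelay movement onset relative to trial onset (s).
#' @param epoch movement-epoch length (s).
#' @param params list with \code{baseline} (Hz), \code{modulation} (Hz) and
#'   optional \code{prefDirection} (deg).
#' @param seed integer root seed.
#' @return list with \code{session} and per-unit \code{truth}.
#' @export
genDirectionSession <- function(nUnits = 8, nTrialsPerDirection = 20,
                                trialDur = 1.5, gap = 0.5, moveDelay = 0.5,
                                epoch = 0.3,
                                params = list(baseline = 5, modulation = 15),
                                seed = 1) {
  dirs <- .directionGrid
  b <- params$baseline; m <- params$modulation
  nTrials <- length(dirs) * nTrialsPerDirection
  tl <- .trialTimeline(nTrials, trialDur, gap)
  duration <- max(tl$offset) + gap
  condSeq <- .withSeed(seed, sample(rep(dirs, each = nTrialsPerDirection)))
  prefs <- if (!is.null(params$prefDirection))
    rep_len(params$prefDirection, nUnits)
  else .withSeed(seed + 20000L, runif(nUnits, 0, 360))
  mo <- tl$onset + moveDelay

  trials <- data.frame(trial_id = seq_len(nTrials), onset = tl$onset,
                       offset = tl$offset, condition_type = "direction",
                       condition = condSeq, grid_x = NA_real_,
                       grid_y = NA_real_, movement_onset = mo,
                       stringsAsFactors = FALSE)

  unitsList <- lapply(seq_len(nUnits), function(i) {
    extra <- m * pmax(0, cos((condSeq - prefs[i]) * pi / 180))
    seg <- rbind(data.frame(start = 0, end = duration, rate = b),
                 data.frame(start = mo, end = mo + epoch, rate = extra))
    st <- .withSeed(seed + i, .poissonPiecewise(seg))
    SortedUnit(sprintf("u%02d", i), unique(st), i)
  })

  session <- RecordingSession(sprintf("dir-seed%d", seed),
                              samplingRate = 20000, duration = duration,
                              trials = trials, units = unitsList)
  truth <- data.frame(unit_id = vapply(unitsList, unitId, character(1)),
                      pref_direction = prefs, baseline = b, modulation = m,
                      stringsAsFactors = FALSE)
  list(session = session, truth = truth, seed = seed)
}

#' Simulate a receptive-field mapping session
#'
#' Small stimulus patches are flashed at grid locations in the visual field
#' (fixation at the origin); each unit responds with a 2D Gaussian spatial
#' profile of rate \eqn{b + A\,\exp(-\|x - c\|^2 / 2\sigma^2)} during the
#' stimulus and baseline \eqn{b} otherwise.
#'
#' @param nUnits number of units.
#' @param gridX,gridY grid coordinates (visual degrees) defining the
#'   stimulus-location lattice.
#' @param nTrialsPerLoc trials per grid location.
#' @param trialDur,gap stimulus duration and inter-trial interval (s).
#' @param params list with \code{baseline}, \code{amplitude} (Hz),
#'   \code{sigma} (deg), and optional per-unit \code{centerX}, \code{centerY}.
#' @param seed root seed.
#' @return list with \code{session} and per-unit \code{truth}.
#' @export
genRfSession <- function(nUnits = 4, gridX = seq(-4, 4, by = 2),
                         gridY = seq(-4, 4, by = 2), nTrialsPerLoc = 8,
                         trialDur = 0.3, gap = 0.3,
                         params = list(baseline = 2, amplitude = 30,
                                       sigma = 1.2),
                         seed = 1) {
  locs <- expand.grid(x = gridX, y = gridY)
  nTrials <- nrow(locs) * nTrialsPerLoc
  tl <- .trialTimeline(nTrials, trialDur, gap)
  duration <- max(tl$offset) + gap
  ord <- .withSeed(seed, sample(rep(seq_len(nrow(locs)), each = nTrialsPerLoc)))
  b <- params$baseline; A <- params$amplitude; sg <- params$sigma
  cx <- if (!is.null(params$centerX)) rep_len(params$centerX, nUnits)
        else .withSeed(seed, runif(nUnits, min(gridX), max(gridX)))
  cy <- if (!is.null(params$centerY)) rep_len(params$centerY, nUnits)
        else .withSeed(seed + 10000L, runif(nUnits, min(gridY), max(gridY)))

  trials <- data.frame(trial_id = seq_len(nTrials), onset = tl$onset,
                       offset = tl$offset, condition_type = "grid",
                       condition = NA_real_, grid_x = locs$x[ord],
                       grid_y = locs$y[ord], movement_onset = NA_real_,
                       stringsAsFactors = FALSE)

  unitsList <- lapply(seq_len(nUnits), function(i) {
    d2 <- (locs$x[ord] - cx[i])^2 + (locs$y[ord] - cy[i])^2
    rates <- b + A * exp(-d2 / (2 * sg^2))
    seg <- rbind(
      data.frame(start = c(0, tl$offset), end = c(tl$onset, duration),
                 rate = b),
      data.frame(start = tl$onset, end = tl$offset, rate = rates))
    st <- .withSeed(seed + i, .poissonPiecewise(seg))
    SortedUnit(sprintf("u%02d", i), unique(st), i)
  })

  session <- RecordingSession(sprintf("rf-seed%d", seed),
                              samplingRate = 20000, duration = duration,
                              trials = trials, units = unitsList)
  truth <- data.frame(unit_id = vapply(unitsList, unitId, character(1)),
                      center_x = cx, center_y = cy, baseline = b,
                      amplitude = A, sigma = sg, stringsAsFactors = FALSE)
  list(session = session, truth = truth, seed = seed)
}

#' Simulate a directionally coupled spike-train pair
#'
#' The leader is homogeneous Poisson. The follower is an independent Poisson
#' train plus, for each leader spike with probability \code{p}, one injected
#' spike at lag \code{lagMs} jittered by N(0, \code{jitterMs}^2). This
#' thinning-and-jitter construction gives an analytically known expected
#' excess-coincidence count (p times the leader spike count) concentrated
#' near +\code{lagMs}, emulating millisecond-scale sequential coactivation.
#'
#' @param rateLeader leader rate (Hz).
#' @param rateFollowerBase follower independent base rate (Hz).
#' @param p injection probability per leader spike, in [0, 1].
#' @param lagMs synaptic-style lag (ms), > 0.
#' @param jitterMs Gaussian jitter SD (ms).
#' @param duration train length (s).
#' @param seed integer seed.
#' @return list with \code{leader}, \code{follower} (sorted spike times, s)
#'   and \code{truth}.
#' @export
genCoupledPair <- function(rateLeader = 10, rateFollowerBase = 10, p = 0.3,
                           lagMs = 2, jitterMs = 0.5, duration = 600,
                           seed = 1) {
  stopifnot(duration > 0, p >= 0, p <= 1, lagMs > 0)
  .withSeed(seed, {
    nl <- rpois(1L, rateLeader * duration)
    leader <- sort(runif(nl, 0, duration))
    base <- sort(runif(rpois(1L, rateFollowerBase * duration), 0, duration))
    take <- runif(nl) < p
    inj <- leader[take] + lagMs / 1000 +
      if (jitterMs > 0) rnorm(sum(take), 0, jitterMs / 1000) else 0
    follower <- sort(c(base, inj))
    follower <- follower[follower >= 0 & follower <= duration]
    list(leader = leader, follower = follower,
         truth = list(p = p, lagMs = lagMs, jitterMs = jitterMs,
                      rateLeader = rateLeader,
                      rateFollowerBase = rateFollowerBase))
  })
}

#' Simulate a broadband trace from spiking units
#'
#' Builds a channels x samples voltage matrix by inserting each unit's
#' waveform template at its spike times (template extremum aligned to the
#' spike sample), with amplitude decaying exponentially with distance from
#' the unit's primary channel, plus white Gaussian noise and optional
#' rectangular high-voltage artifact pulses. Overlapping insertions sum
#' linearly.
#'
#' @param spikeUnits list of lists, each with \code{spikeTimes} (s),
#'   \code{template} (uV vector) and \code{channel} (primary channel index).
#' @param duration trace length (s).
#' @param samplingRate Hz.
#' @param noiseSd white-noise SD (uV).
#' @param artifacts optional data.frame(time, amplitude, duration) of
#'   rectangular pulses applied to every channel.
#' @param channelPositions optional data.frame(channel_id, x, y) in um; when
#'   NULL a single channel (or the max channel index) laid out at 30 um pitch
#'   is assumed.
#' @param spaceConstant exponential amplitude-decay length across channels
#'   (um).
#' @param seed integer seed.
#' @return numeric matrix (channels x samples, uV).
#' @export
genRawTrace <- function(spikeUnits, duration, samplingRate = 20000,
                        noiseSd = 5, artifacts = NULL,
                        channelPositions = NULL, spaceConstant = 50,
                        seed = 1) {
  nSamp <- round(duration * samplingRate)
  if (is.null(channelPositions)) {
    nCh <- max(vapply(spikeUnits, function(u) u$channel, numeric(1)), 1)
    channelPositions <- data.frame(channel_id = seq_len(nCh), x = 0,
                                   y = (seq_len(nCh) - 1) * 30)
  }
  nCh <- nrow(channelPositions)
  trace <- if (noiseSd > 0)
    .withSeed(seed, matrix(rnorm(nCh * nSamp, 0, noiseSd), nrow = nCh))
  else matrix(0, nrow = nCh, ncol = nSamp)

  for (u in spikeUnits) {
    tpl <- u$template
    stopifnot(length(tpl) < nSamp)
    eIdx <- which.max(abs(tpl))
    pc <- match(u$channel, channelPositions$channel_id)
    d <- sqrt((channelPositions$x - channelPositions$x[pc])^2 +
              (channelPositions$y - channelPositions$y[pc])^2)
    scl <- exp(-d / spaceConstant)
    centers <- round(u$spikeTimes * samplingRate) + 1L
    for (cIdx in centers) {
      lo <- cIdx - eIdx + 1L
      hi <- lo + length(tpl) - 1L
      if (lo < 1L || hi > nSamp) next
      for (ch in seq_len(nCh))
        if (scl[ch] > 1e-3)
          trace[ch, lo:hi] <- trace[ch, lo:hi] + scl[ch] * tpl
    }
  }

  if (!is.null(artifacts) && nrow(artifacts)) {
    for (i in seq_len(nrow(artifacts))) {
      lo <- max(1L, round(artifacts$time[i] * samplingRate) + 1L)
      hi <- min(nSamp, lo + round(artifacts$duration[i] * samplingRate) - 1L)
      trace[, lo:hi] <- trace[, lo:hi] + artifacts$amplitude[i]
    }
  }
  trace
}

#' Simulate waveform snippets across drifting sessions
#'
#' Session k's snippets are the template scaled by (1 + (k-1) * drift) plus
#' per-snippet white Gaussian noise, emulating gradual electrode/tissue drift
#' across chronic recording days.
#'
#' @param template mean waveform (uV vector).
#' @param nSessions number of sessions.
#' @param driftPerSession fractional amplitude change per session, >= 0.
#' @param noiseSd per-sample snippet noise SD (uV).
#' @param nSnippets snippets per session.
#' @param seed integer seed.
#' @return list of snippet matrices (nSnippets x length(template)).
#' @export
genMultisessionDrift <- function(template, nSessions = 3,
                                 driftPerSession = 0, noiseSd = 3,
                                 nSnippets = 200, seed = 1) {
  stopifnot(driftPerSession >= 0)
  lapply(seq_len(nSessions), function(k) {
    scl <- 1 + (k - 1) * driftPerSession
    .withSeed(seed + k, {
      noise <- matrix(rnorm(nSnippets * length(template), 0, noiseSd),
                      nrow = nSnippets)
      sweep(noise, 2, scl * template, "+")
    })
  })
}

#' Simulate center-out cursor trials
#'
#' The cursor starts at the screen center and steps toward the target with
#' Gaussian heading noise; a trial succeeds when the cursor center enters the
#' target disk before the timeout. Geometry defaults follow the task layout:
#' targets 7.5 cm from the center, 3.7 cm diameter, 8 directions at 45
#' degrees.
#'
#' @param nTrials number of trials (targets cycle through the 8 directions).
#' @param mode "hand" or "brain" (label only; the kinematic model is shared).
#' @param noiseLevel heading-noise SD in radians per step.
#' @param speed cursor speed (cm/s).
#' @param dt sample interval (s).
#' @param targetDistance,targetRadius,timeout task geometry (cm, cm, s).
#' @param seed integer seed.
#' @return list of \linkS4class{CursorTrial}.
#' @export
genCursorTrials <- function(nTrials = 40, mode = "hand", noiseLevel = 0.2,
                            speed = 6, dt = 0.05, targetDistance = 7.5,
                            targetRadius = 1.85, timeout = 10, seed = 1) {
  dirs <- rep_len(.directionGrid, nTrials)
  .withSeed(seed, lapply(seq_len(nTrials), function(i) {
    tgt <- targetDistance * c(cos(dirs[i] * pi / 180),
                              sin(dirs[i] * pi / 180))
    nMax <- ceiling(timeout / dt)
    pos <- matrix(NA_real_, nrow = nMax + 1L, ncol = 2)
    pos[1, ] <- c(0, 0)
    success <- FALSE
    k <- 1L
    while (k <= nMax) {
      aim <- atan2(tgt[2] - pos[k, 2], tgt[1] - pos[k, 1])
      if (noiseLevel > 0) aim <- aim + rnorm(1, 0, noiseLevel)
      pos[k + 1L, ] <- pos[k, ] + speed * dt * c(cos(aim), sin(aim))
      k <- k + 1L
      if (sqrt(sum((pos[k, ] - tgt)^2)) <= targetRadius) {
        success <- TRUE
        break
      }
    }
    CursorTrial(times = (seq_len(k) - 1L) * dt, positions = pos[seq_len(k), ],
                targetDirection = dirs[i], targetDistance = targetDistance,
                targetRadius = targetRadius, mode = mode, success = success,
                timeout = timeout)
  }))
}
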