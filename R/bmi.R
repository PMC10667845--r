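# Center-out task metrics (accuracy, time cost, path efficiency), the
# hand-versus-brain comparison statistics (two-tailed bootstrap of the
# success proportion, Mann-Whitney U for time cost and path efficiency, both
# FDR-adjusted), and a plumbing ridge velocity decoder plus closed-loop
# simulator so that brain-control metrics can be exercised end to end.

.acquisitionIndex <- function(trial) {
  tgt <- trial@targetDistance *
    c(cos(trial@targetDirection * pi / 180),
      sin(trial@targetDirection * pi / 180))
  d <- sqrt((trial@positions[, 1] - tgt[1])^2 +
            (trial@positions[, 2] - tgt[2])^2)
  idx <- which(d <= trial@targetRadius)
  if (length(idx)) idx[1] else NA_integer_
}

#' Path efficiency of a successful trial
#'
#' Ratio of the straight-line distance from the start position to the point
#' of target acquisition (first sample inside the target disk) over the
#' actual path length traveled up to that sample. Bounded above by 1 by the
#' triangle inequality, and invariant under rigid rotation or translation of
#' the trajectory.
#'
#' @param trial a successful \linkS4class{CursorTrial} with >= 2 samples.
#' @return efficiency in (0, 1]; NA (with a warning) for zero traveled
#'   distance.
#' @export
pathEfficiency <- function(trial) {
  stopifnot(is(trial, "CursorTrial"), isTRUE(trial@success))
  k <- .acquisitionIndex(trial)
  stopifnot(!is.na(k), k >= 2L)
  p <- trial@positions[seq_len(k), , drop = FALSE]
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  traveled <- sum(seg)
  if (traveled == 0) {
    warning("zero traveled distance; path efficiency undefined")
    return(NA_real_)
  }
  sqrt((p[k, 1] - p[1, 1])^2 + (p[k, 2] - p[1, 2])^2) / traveled
}

#' Time cost of a successful trial
#'
#' Time from trial start to target acquisition (first sample inside the
#' target disk).
#'
#' @param trial a successful \linkS4class{CursorTrial}.
#' @return seconds.
#' @export
timeCost <- function(trial) {
  stopifnot(is(trial, "CursorTrial"), isTRUE(trial@success))
  k <- .acquisitionIndex(trial)
  stopifnot(!is.na(k))
  trial@times[k] - trial@times[1]
}

#' Per-direction task accuracy
#'
#' Successes over attempts for each target direction present in the trial
#' set; directions with no attempts are simply absent. The pooled accuracy
#' equals the trial-weighted mean of the per-direction accuracies.
#'
#' @param trialsList list of \linkS4class{CursorTrial}.
#' @return data.frame with direction, n_attempts, n_success, accuracy.
#' @export
taskAccuracy <- function(trialsList) {
  dir <- vapply(trialsList, function(t) t@targetDirection, numeric(1))
  suc <- vapply(trialsList, function(t) isTRUE(t@success), logical(1))
  dd <- sort(unique(dir))
  data.frame(direction = dd,
             n_attempts = vapply(dd, function(d) sum(dir == d), integer(1)),
             n_success = vapply(dd, function(d) sum(suc[dir == d]),
                                integer(1)),
             accuracy = vapply(dd, function(d) mean(suc[dir == d]),
                               numeric(1)))
}

#' Summarise task metrics for a trial set
#'
#' @param trialsList list of \linkS4class{CursorTrial}.
#' @return data.frame with one row per trial: direction, mode, success,
#'   time_cost (NA for failures), path_efficiency (NA for failures).
#' @export
taskMetrics <- function(trialsList) {
  do.call(rbind, lapply(trialsList, function(t) {
    okTrial <- isTRUE(t@success)
    data.frame(direction = t@targetDirection, mode = t@mode,
               success = okTrial,
               time_cost = if (okTrial) timeCost(t) else NA_real_,
               path_efficiency = if (okTrial) pathEfficiency(t) else
                 NA_real_, stringsAsFactors = FALSE)
  }))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment (p(i) * m / i with cumulative
#' minimum enforcement); adjusted values never fall below the raw ones.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# two-tailed bootstrap p for a difference in success proportions: resample
# trials with replacement within each mode, center the bootstrap difference
# distribution, and count exceedances of the observed difference.
.bootstrapProportionP <- function(sucA, sucB, nBoot = 2000) {
  obs <- mean(sucA) - mean(sucB)
  dstar <- vapply(seq_len(nBoot), function(i)
    mean(sample(sucA, replace = TRUE)) - mean(sample(sucB, replace = TRUE)),
    numeric(1))
  centered <- dstar - mean(dstar)
  (1 + sum(abs(centered) >= abs(obs))) / (nBoot + 1)
}

#' Compare hand- and brain-control performance
#'
#' Per target direction, accuracy is compared by a two-tailed bootstrap of
#' the success-proportion difference (2000 resamples by default, seeded);
#' time cost and path efficiency (successful trials only) are compared by
#' two-sided Mann-Whitney U tests. Each metric's per-direction p-values are
#' Benjamini-Hochberg adjusted.
#'
#' @param handTrials,brainTrials lists of \linkS4class{CursorTrial}.
#' @param nBoot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with direction and, per metric, the raw and
#'   FDR-adjusted p-value (accuracy_p, accuracy_p_adj, time_p, time_p_adj,
#'   path_p, path_p_adj).
#' @export
compareModes <- function(handTrials, brainTrials, nBoot = 2000, seed = 1) {
  mh <- taskMetrics(handTrials)
  mb <- taskMetrics(brainTrials)
  dirs <- sort(intersect(unique(mh$direction), unique(mb$direction)))
  stopifnot(length(dirs) > 0)
  mwP <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 1L || length(b) < 1L) return(NA_real_)
    if (length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(wilcox.test(a, b)$p.value)
  }
  res <- .withSeed(seed, {
    rows <- lapply(dirs, function(d) {
      h <- mh[mh$direction == d, ]; b <- mb[mb$direction == d, ]
      data.frame(direction = d,
                 accuracy_p = .bootstrapProportionP(h$success, b$success,
                                                    nBoot),
                 time_p = mwP(h$time_cost, b$time_cost),
                 path_p = mwP(h$path_efficiency, b$path_efficiency))
    })
    do.call(rbind, rows)
  })
  res$accuracy_p_adj <- bhFdr(res$accuracy_p)
  res$time_p_adj <- bhFdr(res$time_p)
  res$path_p_adj <- bhFdr(res$path_p)
  res[, c("direction", "accuracy_p", "accuracy_p_adj", "time_p",
          "time_p_adj", "path_p", "path_p_adj")]
}

#' Train a ridge velocity decoder
#'
#' Linear map from binned spike counts to 2D cursor velocity minimizing the
#' ridge-penalized squared error; a plumbing decoder used to close the loop
#' in simulation (the intercept is unpenalized). Deterministic given its
#' inputs.
#'
#' @param counts T x n_units matrix of binned counts.
#' @param velocities T x 2 matrix of cursor velocities (cm/s).
#' @param lambda ridge penalty (0 = ordinary least squares).
#' @return list (class "velocityDecoder") with weights (n_units x 2) and
#'   intercept (length 2).
#' @export
trainVelocityDecoder <- function(counts, velocities, lambda = 1e-6) {
  stopifnot(nrow(counts) == nrow(velocities), ncol(velocities) == 2L)
  xm <- colMeans(counts)
  vm <- colMeans(velocities)
  xc <- sweep(counts, 2, xm, "-")
  vc <- sweep(velocities, 2, vm, "-")
  w <- solve(crossprod(xc) + lambda * diag(ncol(counts)), crossprod(xc, vc))
  out <- list(weights = w, intercept = vm - as.numeric(crossprod(w, xm)))
  class(out) <- "velocityDecoder"
  out
}

#' Predict velocities from counts
#'
#' @param object a \code{\link{trainVelocityDecoder}} fit.
#' @param newdata T x n_units count matrix.
#' @param ... ignored.
#' @return T x 2 velocity matrix.
#' @export
predict.velocityDecoder <- function(object, newdata, ...) {
  sweep(newdata %*% object$weights, 2, object$intercept, "+")
}

#' Simulate closed-loop brain control of the cursor
#'
#' At each 50 ms step the cosine-tuned synthetic population modulates its
#' rates toward the current target direction, spike counts are drawn
#' (Poisson, or their expectation when \code{noiseless}), the decoder maps
#' counts to a velocity, and the cursor integrates it; the trial succeeds
#' when the cursor center enters the target disk before the timeout.
#'
#' @param decoder a \code{\link{trainVelocityDecoder}} fit.
#' @param population list with \code{pref} (per-unit preferred direction,
#'   deg), \code{baseline} (Hz) and \code{modulation} (Hz).
#' @param targets target directions (deg), one per trial.
#' @param dt step (s).
#' @param targetDistance,targetRadius,timeout geometry (cm, cm, s).
#' @param noiseless use expected counts instead of Poisson draws.
#' @param seed integer seed.
#' @return list of \linkS4class{CursorTrial} with mode "brain".
#' @export
simulateClosedLoop <- function(decoder, population, targets, dt = 0.05,
                               targetDistance = 7.5, targetRadius = 1.85,
                               timeout = 10, noiseless = FALSE, seed = 1) {
  .withSeed(seed, lapply(targets, function(dirDeg) {
    tgt <- targetDistance * c(cos(dirDeg * pi / 180),
                              sin(dirDeg * pi / 180))
    nMax <- ceiling(timeout / dt)
    pos <- matrix(NA_real_, nrow = nMax + 1L, ncol = 2)
    pos[1, ] <- c(0, 0)
    success <- FALSE
    k <- 1L
    while (k <= nMax) {
      aim <- atan2(tgt[2] - pos[k, 2], tgt[1] - pos[k, 1]) * 180 / pi
      lam <- (population$baseline + population$modulation *
                pmax(0, cos((aim - population$pref) * pi / 180))) * dt
      cnt <- if (noiseless) lam else rpois(length(lam), lam)
      v <- as.numeric(predict(decoder, matrix(cnt, nrow = 1)))
      pos[k + 1L, ] <- pos[k, ] + v * dt
      k <- k + 1L
      if (sqrt(sum((pos[k, ] - tgt)^2)) <= targetRadius) {
        success <- TRUE
        break
      }
    }
    CursorTrial(times = (seq_len(k) - 1L) * dt,
                positions = pos[seq_len(k), ], targetDirection = dirDeg,
                targetDistance = targetDistance, targetRadius = targetRadius,
                mode = "brain", success = success, timeout = timeout)
  }))
}

#' Generate open-loop training data for the velocity decoder
#'
#' Simulates the cosine-tuned population while the intended velocity sweeps
#' uniformly over directions at a fixed speed, yielding aligned
#' (counts, velocity) samples for \code{\link{trainVelocityDecoder}}.
#'
#' @param population list with pref, baseline, modulation (see
#'   \code{\link{simulateClosedLoop}}).
#' @param nSamples number of 50 ms samples.
#' @param speed intended speed (cm/s).
#' @param dt bin (s).
#' @param noiseless use expected counts.
#' @param seed integer seed.
#' @return list with counts (T x n) and velocities (T x 2).
#' @export
genDecoderTrainingData <- function(population, nSamples = 2000, speed = 6,
                                   dt = 0.05, noiseless = FALSE, seed = 1) {
  .withSeed(seed, {
    dirs <- runif(nSamples, 0, 360)
    lam <- outer(dirs, population$pref, function(d, p)
      population$baseline + population$modulation *
        pmax(0, cos((d - p) * pi / 180))) * dt
    counts <- if (noiseless) lam else
      matrix(rpois(length(lam), lam), nrow = nSamples)
    vel <- speed * cbind(cos(dirs * pi / 180), sin(dirs * pi / 180))
    list(counts = counts, velocities = vel)
  })
}
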