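# Orientation tuning, orientation selectivity, receptive-field mapping and
# the RF-size-versus-depth mixed-effects model for visual units.

#' Per-trial firing rates
#'
#' Spike count inside a window relative to each trial's onset, divided by
#' the window length.
#'
#' @param spikeTimes spike times (s).
#' @param trialTable session trial table (see
#'   \linkS4class{RecordingSession}).
#' @param window c(start, end) in seconds relative to trial onset; defaults
#'   to the full stimulus interval per trial.
#' @return numeric rate (Hz) per trial row.
#' @export
trialRates <- function(spikeTimes, trialTable, window = NULL) {
  vapply(seq_len(nrow(trialTable)), function(i) {
    lo <- trialTable$onset[i] + if (is.null(window)) 0 else window[1]
    hi <- if (is.null(window)) trialTable$offset[i] else
      trialTable$onset[i] + window[2]
    sum(spikeTimes >= lo & spikeTimes < hi) / (hi - lo)
  }, numeric(1))
}

#' Orientation tuning curve
#'
#' Per-orientation mean rate, SEM (SD / sqrt(n)) and rate normalized by the
#' most active orientation's mean, as conventionally plotted for grating
#' responses. With a single trial per condition the SEM is reported as 0
#' with a warning.
#'
#' @param rates per-trial rates (Hz).
#' @param orientations per-trial orientation (deg, on [0, 180)).
#' @return data.frame (class "tuningCurve") with columns condition,
#'   mean_rate, sem, normalized, n_trials, sorted by condition.
#' @export
orientationCurve <- function(rates, orientations) {
  stopifnot(length(rates) == length(orientations))
  conds <- sort(unique(orientations))
  if (length(conds) < 2L) stop("need >= 2 orientations")
  mean_rate <- vapply(conds, function(o) mean(rates[orientations == o]),
                      numeric(1))
  n_trials <- vapply(conds, function(o) sum(orientations == o), integer(1))
  sem <- vapply(conds, function(o) {
    r <- rates[orientations == o]
    if (length(r) < 2L) 0 else sd(r) / sqrt(length(r))
  }, numeric(1))
  if (any(n_trials < 2L))
    warning("single-trial conditions: SEM reported as 0")
  mx <- max(mean_rate)
  curve <- data.frame(condition = conds, mean_rate = mean_rate, sem = sem,
                      normalized = if (mx > 0) mean_rate / mx else
                        rep(0, length(conds)),
                      n_trials = n_trials)
  class(curve) <- c("tuningCurve", "data.frame")
  curve
}

#' Orientation selectivity index
#'
#' OSI = (Rpref - Rorth) / (Rpref + Rorth), where Rpref is the mean rate at
#' the most active orientation and Rorth the mean rate at the grid
#' orientation nearest to 90 degrees away. Lies in [0, 1] for non-negative
#' rates; units with OSI > 0.3 are conventionally called
#' orientation-selective (the gate is strict, so OSI = 0.3 exactly fails).
#'
#' @param curve a tuning curve from \code{\link{orientationCurve}}.
#' @return OSI in [0, 1] (0 for an unresponsive unit).
#' @export
osi <- function(curve) {
  ip <- which.max(curve$mean_rate)
  rp <- curve$mean_rate[ip]
  if (rp <= 0) return(0)
  orthTarget <- (curve$condition[ip] + 90) %% 180
  dAng <- abs(((curve$condition - orthTarget + 90) %% 180) - 90)
  ro <- curve$mean_rate[which.min(dAng)]
  (rp - ro) / (rp + ro)
}

#' Preferred orientation of a tuning curve
#'
#' Half-angle of the rate-weighted doubled-angle vector sum,
#' 0.5 * atan2(sum R sin 2t, sum R cos 2t), mapped to [0, 180). Flat or
#' symmetric curves with a (near-)zero resultant return NA. Equivariant:
#' rotating all stimulus orientations by delta rotates the estimate by
#' delta (mod 180).
#'
#' @param curve tuning curve from \code{\link{orientationCurve}}.
#' @param tol resultant-length tolerance below which NA is returned
#'   (relative to the summed rates).
#' @return preferred orientation (deg) or NA.
#' @export
preferredOrientation <- function(curve, tol = 1e-8) {
  th <- curve$condition * pi / 180
  sx <- sum(curve$mean_rate * cos(2 * th))
  sy <- sum(curve$mean_rate * sin(2 * th))
  tot <- sum(abs(curve$mean_rate))
  if (tot == 0 || sqrt(sx^2 + sy^2) < tol * tot) return(NA_real_)
  (0.5 * atan2(sy, sx) * 180 / pi) %% 180
}

#' Receptive-field response grid
#'
#' Mean evoked rate per stimulus grid location minus the unit's baseline
#' rate, where the baseline is taken from an equal-length window immediately
#' before each stimulus onset.
#'
#' @param spikeTimes spike times (s).
#' @param trialTable trial table with condition_type "grid" rows (grid_x,
#'   grid_y in visual degrees, fixation at the origin).
#' @return data.frame with x, y, rate (baseline-subtracted Hz) and n_trials,
#'   one row per grid location.
#' @export
rfMap <- function(spikeTimes, trialTable) {
  tr <- trialTable[trialTable$condition_type == "grid", , drop = FALSE]
  stopifnot(nrow(tr) > 0)
  dur <- tr$offset - tr$onset
  evoked <- vapply(seq_len(nrow(tr)), function(i)
    sum(spikeTimes >= tr$onset[i] & spikeTimes < tr$offset[i]) / dur[i],
    numeric(1))
  base <- vapply(seq_len(nrow(tr)), function(i)
    sum(spikeTimes >= tr$onset[i] - dur[i] & spikeTimes < tr$onset[i]) /
      dur[i], numeric(1))
  resp <- evoked - base
  key <- paste(tr$grid_x, tr$grid_y, sep = "/")
  agg <- aggregate(resp, by = list(key = key), FUN = mean)
  cnt <- as.integer(table(key)[agg$key])
  xy <- do.call(rbind, strsplit(agg$key, "/", fixed = TRUE))
  out <- data.frame(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]),
                    rate = agg$x, n_trials = cnt)
  out[order(out$y, out$x), , drop = FALSE]
}

#' Fit an elliptical Gaussian receptive field
#'
#' Least-squares fit of A * exp(-((x-x0)^2/(2 sx^2) + (y-y0)^2/(2 sy^2))) +
#' c to the response grid. RF size is defined from the fit as
#' 2 * sqrt(sx * sy) (geometric-mean diameter at one sigma); eccentricity is
#' the distance of the fitted center from fixation at (0, 0). The fit is
#' marked not-ok when the grid peak is below twice the grid noise SD, the
#' optimizer fails, or the center leaves the sampled grid.
#'
#' @param grid data.frame from \code{\link{rfMap}} (columns x, y, rate).
#' @return list with center (x, y deg), size (deg), eccentricity (deg),
#'   sigmaX, sigmaY, amplitude, fitOk and the residual SD.
#' @export
rfFit <- function(grid) {
  bad <- list(center = c(NA_real_, NA_real_), size = NA_real_,
              eccentricity = NA_real_, sigmaX = NA_real_, sigmaY = NA_real_,
              amplitude = NA_real_, fitOk = FALSE, residSd = NA_real_)
  r <- grid$rate
  if (max(r) <= 0) return(bad)
  noiseSd <- sd(r[r <= median(r)])
  if (is.na(noiseSd)) noiseSd <- 0
  ip <- which.max(r)
  gx <- sort(unique(grid$x)); gy <- sort(unique(grid$y))
  spacing <- mean(c(diff(gx), diff(gy)))
  start <- list(A = max(r), x0 = grid$x[ip], y0 = grid$y[ip],
                sx = spacing, sy = spacing, c0 = min(r))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ A * exp(-((x - x0)^2 / (2 * sx^2) +
                       (y - y0)^2 / (2 * sy^2))) + c0,
      data = grid, start = start,
      lower = c(A = 0, x0 = min(gx) - spacing, y0 = min(gy) - spacing,
                sx = 1e-3, sy = 1e-3, c0 = -Inf),
      upper = c(A = Inf, x0 = max(gx) + spacing, y0 = max(gy) + spacing,
                sx = diff(range(gx)) + spacing,
                sy = diff(range(gy)) + spacing, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- coef(fit)
  ok <- max(r) >= 2 * noiseSd && cf["A"] > 0
  list(center = unname(cf[c("x0", "y0")]),
       size = unname(2 * sqrt(cf["sx"] * cf["sy"])),
       eccentricity = unname(sqrt(cf["x0"]^2 + cf["y0"]^2)),
       sigmaX = unname(cf["sx"]), sigmaY = unname(cf["sy"]),
       amplitude = unname(cf["A"]), fitOk = ok,
       residSd = sd(residuals(fit)))
}

#' Mixed-effects model of RF size versus cortical depth
#'
#' Fits RF_size ~ depth with a random intercept and an (uncorrelated) random
#' slope per shank, and tests the fixed depth slope against zero
#' (Satterthwaite degrees of freedom). When the random-slope fit is singular
#' or fails to converge, the model falls back to a random-intercept-only fit
#' and flags it.
#'
#' @param rfSizes RF sizes (deg).
#' @param depths recording-site depths (um below the pia, or any monotone
#'   depth coordinate).
#' @param shankIds shank identifier per unit.
#' @return list with slope (per depth unit), ci (95% Wald), p, singular
#'   (logical: fell back to random intercept only) and the fitted model.
#' @export
rfDepthModel <- function(rfSizes, depths, shankIds) {
  stopifnot(length(rfSizes) == length(depths),
            length(depths) == length(shankIds))
  if (length(unique(shankIds)) < 2L) stop("need >= 2 shanks")
  df <- data.frame(size = rfSizes, depth = depths,
                   shank = factor(shankIds))
  fitQuiet <- function(form) suppressWarnings(suppressMessages(
    tryCatch(lmerTest::lmer(form, data = df, REML = TRUE),
             error = function(e) NULL)))
  fit <- fitQuiet(size ~ depth + (1 | shank) + (0 + depth | shank))
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) fit <- fitQuiet(size ~ depth + (1 | shank))
  if (is.null(fit)) stop("mixed model failed to fit")
  sm <- summary(fit)$coefficients
  slope <- sm["depth", "Estimate"]
  se <- sm["depth", "Std. Error"]
  p <- sm["depth", "Pr(>|t|)"]
  # t-quantile at the Satterthwaite df: with few shanks the normal
  # quantile understates the CI
  tq <- qt(0.975, df = sm["depth", "df"])
  list(slope = slope, ci = slope + c(-1, 1) * tq * se, p = p,
       singular = singular, model = fit)
}
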