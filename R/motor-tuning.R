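# Preferred movement direction of motor-cortical units from the 8-target
# center-out task: firing rates in the 0-300 ms post-movement-onset epoch,
# summed as a max-normalized vector over the 8 directions
#   FRx = sum_i (FR_i / max_j FR_j) cos(theta_i)
#   FRy = sum_i (FR_i / max_j FR_j) sin(theta_i)
# with the preferred direction and preference strength given by the angle
# and length of [FRx, FRy].

#' Movement-epoch firing rates per target direction
#'
#' Mean rate in [movement_onset, movement_onset + epoch] for each of the 8
#' target directions. Directions with no trials raise an error naming the
#' direction (they are never imputed).
#'
#' @param spikeTimes spike times (s).
#' @param trialTable trial table with condition_type "direction" rows and
#'   movement_onset set.
#' @param epoch epoch length after movement onset (s), default 0.3.
#' @return named numeric vector of mean rates (Hz), one per direction in
#'   {0, 45, ..., 315}.
#' @export
epochRates <- function(spikeTimes, trialTable, epoch = 0.3) {
  tr <- trialTable[trialTable$condition_type == "direction", , drop = FALSE]
  stopifnot(nrow(tr) > 0, all(!is.na(tr$movement_onset)))
  missing <- setdiff(.directionGrid, tr$condition)
  if (length(missing))
    stop("no trials for direction(s): ", paste(missing, collapse = ", "))
  rates <- vapply(seq_len(nrow(tr)), function(i) {
    lo <- tr$movement_onset[i]
    sum(spikeTimes >= lo & spikeTimes < lo + epoch) / epoch
  }, numeric(1))
  out <- vapply(.directionGrid, function(d) mean(rates[tr$condition == d]),
                numeric(1))
  names(out) <- .directionGrid
  out
}

#' Preferred direction and preference strength
#'
#' Max-normalized vector sum of the 8 per-direction rates (see the module
#' header): the preferred direction is atan2(FRy, FRx) mapped to [0, 360)
#' and the preference strength is the vector length sqrt(FRx^2 + FRy^2).
#' Uniform rates across the 8 equispaced directions sum to the zero vector:
#' the direction is then undefined (NA) with strength 0, as it is when all
#' rates are zero. Scale-invariant in the rates, and equivariant under
#' cyclic rotation of the direction labels.
#'
#' @param rates numeric vector of 8 mean rates (Hz), ordered as
#'   \code{directions}.
#' @param directions direction grid in degrees (default 0, 45, ..., 315).
#' @param tol resultant length below which the direction is declared
#'   undefined.
#' @return list with frx, fry, preferred_direction (deg or NA) and strength.
#' @export
preferredDirection <- function(rates, directions = .directionGrid,
                               tol = 1e-9) {
  stopifnot(length(rates) == length(directions), length(rates) == 8L)
  mx <- max(rates)
  if (mx <= 0)
    return(list(frx = 0, fry = 0, preferred_direction = NA_real_,
                strength = 0))
  w <- rates / mx
  th <- directions * pi / 180
  frx <- sum(w * cos(th))
  fry <- sum(w * sin(th))
  strength <- sqrt(frx^2 + fry^2)
  pd <- if (strength < tol) NA_real_ else (atan2(fry, frx) * 180 / pi) %% 360
  list(frx = frx, fry = fry, preferred_direction = pd,
       strength = if (strength < tol) 0 else strength)
}

#' Direction tuning for every unit of a session
#'
#' Convenience wrapper: movement-epoch rates and the preferred-direction
#' vector for each unit of a center-out session.
#'
#' @param session a \linkS4class{RecordingSession} with direction trials.
#' @param epoch epoch length (s).
#' @return data.frame with unit_id, preferred_direction, strength, frx, fry.
#' @export
directionTuning <- function(session, epoch = 0.3) {
  rows <- lapply(units(session), function(u) {
    fr <- epochRates(spikeTimes(u), trials(session), epoch)
    pd <- preferredDirection(fr)
    data.frame(unit_id = unitId(u),
               preferred_direction = pd$preferred_direction,
               strength = pd$strength, frx = pd$frx, fry = pd$fry,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
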