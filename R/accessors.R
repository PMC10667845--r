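#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))

#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))

#' @rdname accessors
#' @export
setGeneric("primaryChannel", function(x) standardGeneric("primaryChannel"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname accessors
#' @export
setGeneric("units", function(x) standardGeneric("units"))

#' @rdname accessors
#' @export
setGeneric("dayPostImplant", function(x) standardGeneric("dayPostImplant"))

#' @rdname accessors
#' @export
setGeneric("rawTraces", function(x) standardGeneric("rawTraces"))

#' @rdname accessors
#' @export
setGeneric("coupled", function(x) standardGeneric("coupled"))

#' Accessors for the core containers
#'
#' Slot accessors for \linkS4class{SortedUnit}, \linkS4class{RecordingSession},
#' \linkS4class{CursorTrial} and \linkS4class{CCGResult}. Use these rather than
#' \code{@} slot access.
#'
#' @param x the object.
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("spikeTimes", "SortedUnit", function(x) x@spikeTimes)

#' @rdname accessors
#' @export
setMethod("waveforms", "SortedUnit", function(x) x@waveforms)

#' @rdname accessors
#' @export
setMethod("unitId", "SortedUnit", function(x) x@unitId)

#' @rdname accessors
#' @export
setMethod("primaryChannel", "SortedUnit", function(x) x@primaryChannel)

#' @rdname accessors
#' @export
setMethod("nSpikes", "SortedUnit", function(x) length(x@spikeTimes))

#' @rdname accessors
#' @export
setMethod("sessionId", "RecordingSession", function(x) x@sessionId)

#' @rdname accessors
#' @export
setMethod("samplingRate", "RecordingSession", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("sessionDuration", "RecordingSession", function(x) x@duration)

#' @rdname accessors
#' @export
setMethod("channels", "RecordingSession", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("trials", "RecordingSession", function(x) x@trials)

#' @rdname accessors
#' @export
setMethod("units", "RecordingSession", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("dayPostImplant", "RecordingSession", function(x) x@dayPostImplant)

#' @rdname accessors
#' @export
setMethod("rawTraces", "RecordingSession", function(x) x@raw)

#' @rdname accessors
#' @export
setMethod("coupled", "CCGResult", function(x) x@coupled)

setMethod("show", "SortedUnit", function(object) {
  cat("SortedUnit", object@unitId, "\n")
  cat("  ", length(object@spikeTimes), "spikes on channel",
      object@primaryChannel, "\n")
  if (nrow(object@waveforms))
    cat("  ", nrow(object@waveforms), "waveform snippets x",
        ncol(object@waveforms), "samples\n")
  invisible(NULL)
})

setMethod("show", "RecordingSession", function(object) {
  cat("RecordingSession", object@sessionId, "\n")
  cat(sprintf("  %.6g s at %g Hz, day %s post implant\n", object@duration,
              object@samplingRate, object@dayPostImplant))
  cat("  ", nrow(object@channels), "channels,", length(object@units),
      "units,", nrow(object@trials), "trials\n")
  if (!is.null(object@raw))
    cat("  raw:", nrow(object@raw), "x", ncol(object@raw), "samples\n")
  invisible(NULL)
})

setMethod("show", "CursorTrial", function(object) {
  cat(sprintf("CursorTrial (%s control): target %g deg at %g cm, %s\n",
              object@mode, object@targetDirection, object@targetDistance,
              if (isTRUE(object@success)) "success" else "failure"))
  invisible(NULL)
})

setMethod("show", "CCGResult", function(object) {
  cat("CCGResult:", sum(object@counts), "coincidences in",
      length(object@lags), "bins\n")
  cat(sprintf("  peak %d at %+.1f ms, p+ = %.3g, p- = %.3g -> %s\n",
              as.integer(object@peakCount), object@peakLag,
              object@pPositive, object@pNegative,
              if (object@coupled) object@direction else "not coupled"))
  invisible(NULL)
})
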