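# On-disk interchange: a session directory holding
#   session.json   metadata sidecar (schema_version 1, fixed field order)
#   trials.csv     trial table, full-precision "%.17g" floats
#   spikes.csv     unit_id, time_s for every spike
#   waveforms.bin  float32 little-endian snippets, shapes in the sidecar
#   raw.bin        optional float32 little-endian traces (channel-major)
# The layout is deterministic: identical sessions produce identical bytes.

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.writeTable <- function(df, path, numCols) {
  out <- df
  for (nm in numCols) out[[nm]] <- .fmtNum(df[[nm]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, sep = "\n")
  if (nrow(out)) {
    rows <- do.call(paste, c(lapply(out, as.character), sep = ","))
    writeLines(rows, con, sep = "\n")
  }
  invisible(NULL)
}

#' Write a session directory
#'
#' Serializes a \linkS4class{RecordingSession} to the package interchange
#' format: a directory with a versioned JSON sidecar, CSV trial and spike
#' tables, and float32 little-endian binaries for waveform snippets and
#' (optionally) raw traces. The byte layout is deterministic given an
#' identical session, so reruns of a seeded pipeline can be diffed.
#'
#' @param session a \linkS4class{RecordingSession}.
#' @param path directory to create (must be creatable/writable).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{loadSession}}
#' @export
saveSession <- function(session, path) {
  stopifnot(is(session, "RecordingSession"))
  validObject(session)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create session directory: ", path)

  units <- session@units
  meta <- list(
    schema_version = 1L,
    session_id = session@sessionId,
    sampling_rate = session@samplingRate,
    duration = session@duration,
    day_post_implant = session@dayPostImplant,
    channels = lapply(seq_len(nrow(session@channels)), function(i) {
      ch <- session@channels[i, ]
      list(channel_id = as.integer(ch$channel_id),
           shank_id = as.character(ch$shank_id),
           depth = ch$depth, x = ch$x, y = ch$y)
    }),
    units = lapply(units, function(u) {
      list(unit_id = u@unitId,
           primary_channel = u@primaryChannel,
           n_spikes = length(u@spikeTimes),
           n_waveform_rows = nrow(u@waveforms),
           n_waveform_samples = ncol(u@waveforms),
           isolation = u@isolation,
           noise_overlap = u@noiseOverlap)
    }),
    raw = if (is.null(session@raw)) NULL else
      list(n_channels = nrow(session@raw), n_samples = ncol(session@raw))
  )
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, file.path(path, "session.json"))

  .writeTable(session@trials, file.path(path, "trials.csv"),
              numCols = c("onset", "offset", "condition", "grid_x",
                          "grid_y", "movement_onset"))

  sp <- data.frame(
    unit_id = rep(vapply(units, function(u) u@unitId, character(1)),
                  vapply(units, function(u) length(u@spikeTimes), integer(1))),
    time_s = unlist(lapply(units, function(u) u@spikeTimes)),
    stringsAsFactors = FALSE)
  if (!nrow(sp)) sp <- data.frame(unit_id = character(0), time_s = numeric(0))
  .writeTable(sp, file.path(path, "spikes.csv"), numCols = "time_s")

  con <- file(file.path(path, "waveforms.bin"), open = "wb")
  for (u in units)
    if (length(u@waveforms))
      writeBin(as.numeric(t(u@waveforms)), con, size = 4L, endian = "little")
  close(con)

  if (!is.null(session@raw)) {
    con <- file(file.path(path, "raw.bin"), open = "wb")
    writeBin(as.numeric(t(session@raw)), con, size = 4L, endian = "little")
    close(con)
  }
  invisible(path)
}

.schemaCheck <- function(cond, field) {
  if (!cond) stop("schema error in session.json: field '", field,
                  "' missing or ill-typed", call. = FALSE)
}

#' Read a session directory
#'
#' Loads and fully validates a session written by \code{\link{saveSession}}.
#' Schema problems (missing or ill-typed sidecar fields) raise an error that
#' names the offending field; invariant violations (negative sampling rate,
#' non-monotone spike times, ...) are caught by the class validity methods.
#'
#' @param path session directory.
#' @return A validated \linkS4class{RecordingSession}.
#' @export
loadSession <- function(path) {
  sidecar <- file.path(path, "session.json")
  if (!file.exists(sidecar)) stop("no session.json in ", path)
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)

  .schemaCheck(identical(as.integer(meta$schema_version), 1L), "schema_version")
  .schemaCheck(is.character(meta$session_id), "session_id")
  .schemaCheck(is.numeric(meta$sampling_rate) && meta$sampling_rate > 0,
               "sampling_rate")
  .schemaCheck(is.numeric(meta$duration) && meta$duration >= 0, "duration")

  channels <- if (length(meta$channels)) {
    do.call(rbind, lapply(meta$channels, function(ch) {
      .schemaCheck(!is.null(ch$channel_id), "channels.channel_id")
      data.frame(channel_id = as.integer(ch$channel_id),
                 shank_id = as.character(ch$shank_id),
                 depth = as.numeric(ch$depth), x = as.numeric(ch$x),
                 y = as.numeric(ch$y), stringsAsFactors = FALSE)
    }))
  } else NULL

  trials <- read.csv(file.path(path, "trials.csv"),
                     colClasses = c(trial_id = "integer", onset = "numeric",
                                    offset = "numeric",
                                    condition_type = "character",
                                    condition = "numeric",
                                    grid_x = "numeric", grid_y = "numeric",
                                    movement_onset = "numeric"))
  spikes <- read.csv(file.path(path, "spikes.csv"),
                     colClasses = c(unit_id = "character",
                                    time_s = "numeric"))

  wfcon <- NULL
  wfpath <- file.path(path, "waveforms.bin")
  if (file.exists(wfpath)) wfcon <- file(wfpath, open = "rb")
  on.exit(if (!is.null(wfcon)) close(wfcon))

  unitsList <- lapply(meta$units, function(um) {
    .schemaCheck(is.character(um$unit_id), "units.unit_id")
    st <- spikes$time_s[spikes$unit_id == um$unit_id]
    nwr <- as.integer(um$n_waveform_rows)
    nws <- as.integer(um$n_waveform_samples)
    wf <- matrix(numeric(0), 0, 0)
    if (nwr > 0L) {
      vals <- readBin(wfcon, what = "numeric", n = nwr * nws, size = 4L,
                      endian = "little")
      wf <- matrix(vals, nrow = nwr, ncol = nws, byrow = TRUE)
    }
    SortedUnit(um$unit_id, st, as.integer(um$primary_channel), wf,
               isolation = if (is.null(um$isolation)) NA_real_ else
                 as.numeric(um$isolation),
               noiseOverlap = if (is.null(um$noise_overlap)) NA_real_ else
                 as.numeric(um$noise_overlap))
  })

  raw <- NULL
  if (!is.null(meta$raw)) {
    nc <- as.integer(meta$raw$n_channels)
    ns <- as.integer(meta$raw$n_samples)
    vals <- readBin(file.path(path, "raw.bin"), what = "numeric", n = nc * ns,
                    size = 4L, endian = "little")
    raw <- matrix(vals, nrow = nc, ncol = ns, byrow = TRUE)
  }

  RecordingSession(meta$session_id, meta$sampling_rate, meta$duration,
                   channels = channels, raw = raw, trials = trials,
                   units = unitsList,
                   dayPostImplant = if (is.null(meta$day_post_implant))
                     NA_integer_ else as.integer(meta$day_post_implant))
}
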