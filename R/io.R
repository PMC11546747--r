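# Readers and writers for the pipeline's plain-text dialects. CSV: comma
# separated, UTF-8, header row, '.' decimal separator, times in seconds with
# 6 decimal places. Metrics and ground-truth sidecars are JSON.

#' Write / read a TrialEvents stream as CSV
#'
#' Dialect: header `time_s,event,trial_index`, times with 6 decimals.
#'
#' @param x a \linkS4class{TrialEvents}.
#' @param path file path.
#' @return `writeTrialEvents` returns the path invisibly; `readTrialEvents`
#'   returns a validated \linkS4class{TrialEvents}.
#' @export
writeTrialEvents <- function(x, path) {
  ev <- eventTable(x)
  ev$time_s <- sprintf("%.6f", ev$time_s)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrialEvents
#' @export
readTrialEvents <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "event", "trial_index")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop(sprintf("malformed events header in '%s': expected %s", path,
                 paste(need, collapse = ",")))
  }
  if (is.unsorted(df$time_s)) {
    stop(sprintf("validation error in '%s': event times not non-decreasing",
                 path))
  }
  new("TrialEvents", events = data.frame(time_s = as.numeric(df$time_s),
                                         event = as.character(df$event),
                                         trial_index = as.integer(df$trial_index)))
}

#' Write / read a spike session as CSV plus JSON metadata
#'
#' Spikes go to `<path>` with header `unit_id,spike_time_s`; session
#' metadata (duration, group, sex, planted profiles) to `<path>` with
#' extension replaced by `.meta.json`.
#'
#' @param x a \linkS4class{SpikeSession}.
#' @param path CSV file path.
#' @return the path (write) or a \linkS4class{SpikeSession} (read).
#' @export
writeSpikeSession <- function(x, path) {
  sp <- spikeTimes(x)
  df <- data.frame(
    unit_id = rep(names(sp), vapply(sp, length, integer(1))),
    spike_time_s = sprintf("%.6f", unlist(sp, use.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(duration = sessionDuration(x), group_label = x@groupLabel,
               sex = x@sex, unit_ids = names(sp), profiles = unitProfiles(x))
  jsonlite::write_json(meta, .metaPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.metaPath <- function(path) sub("\\.[^.]*$", ".meta.json", path)

#' @rdname writeSpikeSession
#' @export
readSpikeSession <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("unit_id", "spike_time_s"))) {
    stop(sprintf("malformed spikes header in '%s'", path))
  }
  meta <- jsonlite::read_json(.metaPath(path), simplifyVector = TRUE)
  sp <- split(as.numeric(df$spike_time_s), df$unit_id)
  sp <- lapply(sp, sort)
  ids <- meta$unit_ids %||% names(sp)
  spikes <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) spikes[[id]] <- sp[[id]] %||% numeric()
  new("SpikeSession", spikes = spikes, duration = meta$duration,
      groupLabel = meta$group_label %||% "CTRL", sex = meta$sex %||% "F",
      profiles = as.character(meta$profiles %||% character()))
}

#' Write / read a photometry recording as CSV plus JSON sidecar
#'
#' Columns `signal_470,iso_405`; sampling rate and ground truth go to the
#' `.meta.json` sidecar.
#'
#' @param x a \linkS4class{PhotometryRecording}.
#' @param path CSV file path.
#' @return the path (write) or a \linkS4class{PhotometryRecording} (read).
#' @export
writePhotometry <- function(x, path) {
  df <- data.frame(signal_470 = signalChannel(x), iso_405 = isoChannel(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  gt <- groundTruth(x)
  gt$bleach <- NULL; gt$artifact <- NULL    # keep the sidecar small
  jsonlite::write_json(list(fs_hz = samplingRate(x), t0 = x@t0,
                            ground_truth = gt),
                       .metaPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhotometry
#' @export
readPhotometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("signal_470", "iso_405") %in% names(df))) {
    stop(sprintf("malformed photometry header in '%s'", path))
  }
  meta <- jsonlite::read_json(.metaPath(path), simplifyVector = TRUE)
  new("PhotometryRecording", signal470 = as.numeric(df$signal_470),
      iso405 = as.numeric(df$iso_405), fs = meta$fs_hz,
      t0 = meta$t0 %||% 0,
      groundTruth = as.list(meta$ground_truth %||% list()))
}

#' Load a session bundle from a directory
#'
#' Expects at least `events.csv`; `photometry.csv` and `spikes.csv` (with
#' their `.meta.json` sidecars) are attached when present. Every component
#' is validated on load.
#'
#' @param path directory containing the session files.
#' @return list with `events` (\linkS4class{TrialEvents}), and optionally
#'   `photometry` and `spikes`.
#' @export
loadSessionBundle <- function(path) {
  evp <- file.path(path, "events.csv")
  if (!file.exists(evp)) stop(sprintf("missing events file '%s'", evp))
  out <- list(events = readTrialEvents(evp))
  php <- file.path(path, "photometry.csv")
  if (file.exists(php)) out$photometry <- readPhotometry(php)
  spp <- file.path(path, "spikes.csv")
  if (file.exists(spp)) out$spikes <- readSpikeSession(spp)
  out
}
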