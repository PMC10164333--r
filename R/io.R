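#' @title Plain-text serialization
#' @description
#' Recordings are written as headered CSV (`time_s` plus one column per
#' channel, microvolts) with the annotation table in a companion events
#' CSV (`time_s`, `label`, `trial_index`).  Calibrations serialize to
#' JSON; study configurations to YAML.
#' @name io
NULL

#' Write / read a recording as headered CSV
#'
#' @param recording a [signal_recording()].
#' @param path output CSV path; annotations go to
#'   `<path minus .csv>_events.csv` when present.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns a [signal_recording()].
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "signal_recording"))
  df <- data.frame(time_s = (seq_len(ncol(recording$samples)) - 1L) /
                     recording$fs)
  for (ch in recording$channel_labels)
    df[[ch]] <- recording$samples[ch, ]
  utils::write.csv(df, path, row.names = FALSE)
  if (nrow(recording$annotations))
    write_events_csv(recording$annotations, events_path_for(path))
  invisible(path)
}

events_path_for <- function(path) sub("\\.csv$", "_events.csv", path)

#' @rdname write_recording_csv
#' @param path CSV path written by [write_recording_csv()].
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("time_s" %in% names(df))
  fs <- 1 / stats::median(diff(df$time_s))
  chans <- setdiff(names(df), "time_s")
  ev <- events_path_for(path)
  ann <- if (file.exists(ev)) read_events_csv(ev) else empty_annotations()
  signal_recording(t(as.matrix(df[chans])), round(fs), chans, ann)
}

#' Write / read an event (annotation) table as CSV
#' @param events data frame with columns `time`, `label`, `trial_index`.
#' @param path CSV path.
#' @return The path (write) or the event data frame (read).
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(time_s = events$time, label = events$label,
                   trial_index = events$trial_index)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  data.frame(time = df$time_s, label = df$label,
             trial_index = df$trial_index)
}

#' Serialize calibrations to / from JSON
#' @param cal an `erd_calibration` or `hov_calibration`.
#' @param path JSON file path.
#' @return The path (write) or the calibration object (read).
#' @export
write_calibration_json <- function(cal, path) {
  kind <- class(cal)[1]
  obj <- c(list(kind = kind), unclass(cal))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  obj$kind <- NULL
  structure(obj, class = kind)
}

#' Write a task log as CSV
#' @param log a `task_log`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_task_log_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

# tiny FNV-1a hash for provenance manifests (no external digest dependency)
fnv1a <- function(txt) {
  h <- 2166136261
  for (b in as.integer(charToRaw(txt))) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
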