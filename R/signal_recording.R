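#' Annotated multichannel signal recording
#'
#' Container for a fixed-rate multichannel time series (EEG or EOG) in
#' microvolts, together with an event-annotation table.  Annotations carry a
#' time in seconds, a text label and an optional trial index; they are used to
#' mark cue onsets, ground-truth intent onsets and paced calibration
#' movements.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `samples`.
#' @param annotations data frame with columns `time` (s), `label`,
#'   `trial_index` (may be `NA`).  Defaults to an empty table.
#' @return An object of class `signal_recording` with elements
#'   `samples`, `fs`, `channel_labels`, `annotations`.
#' @export
signal_recording <- function(samples, fs, channel_labels,
                             annotations = empty_annotations()) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(channel_labels) != nrow(samples))
    stop("channel count (", nrow(samples), ") does not match ",
         length(channel_labels), " channel labels")
  annotations <- as_annotations(annotations)
  dur <- ncol(samples) / fs
  if (nrow(annotations) && (any(annotations$time < 0) ||
                            any(annotations$time > dur + 1e-9)))
    stop("annotation times must lie within [0, duration]")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 annotations = annotations),
            class = "signal_recording")
}

empty_annotations <- function() {
  data.frame(time = numeric(0), label = character(0),
             trial_index = integer(0), stringsAsFactors = FALSE)
}

as_annotations <- function(x) {
  if (is.null(x)) return(empty_annotations())
  stopifnot(is.data.frame(x), all(c("time", "label") %in% names(x)))
  if (is.null(x$trial_index)) x$trial_index <- NA_integer_
  x <- x[order(x$time), c("time", "label", "trial_index")]
  rownames(x) <- NULL
  x
}

#' Duration of a recording in seconds
#' @param x a `signal_recording`.
#' @return Length of the recording in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "signal_recording"))
  ncol(x$samples) / x$fs
}

#' Extract one channel as a numeric vector
#' @param x a `signal_recording`.
#' @param label channel label.
#' @return Numeric vector of samples in microvolts.
#' @export
channel <- function(x, label) {
  stopifnot(inherits(x, "signal_recording"))
  i <- match(label, x$channel_labels)
  if (is.na(i)) stop("channel '", label, "' not present in recording")
  x$samples[i, ]
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %d channel(s) x %.1f s @ %g Hz\n",
              nrow(x$samples), duration(x), x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  annotations:", nrow(x$annotations), "event(s)\n")
  invisible(x)
}

#' @export
plot.signal_recording <- function(x, channels = x$channel_labels,
                                  tlim = NULL, ...) {
  tt <- seq_len(ncol(x$samples)) / x$fs
  sel <- if (is.null(tlim)) rep(TRUE, length(tt)) else
    tt >= tlim[1] & tt <= tlim[2]
  old <- graphics::par(mfrow = c(length(channels), 1L),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    graphics::plot(tt[sel], channel(x, ch)[sel], type = "l",
                   xlab = "time (s)", ylab = paste0(ch, " (uV)"), ...)
  }
  invisible(x)
}

# internal: index window of samples covering [t0, t1) seconds
sample_window <- function(x, t0, t1) {
  i0 <- max(1L, floor(t0 * x$fs) + 1L)
  i1 <- min(ncol(x$samples), ceiling(t1 * x$fs))
  i0:i1
}
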