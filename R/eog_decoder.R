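#' @title Horizontal-oculoversion (HOV) detection on bipolar EOG
#' @description
#' Calibration sets the detection threshold at 70% of the mean absolute
#' peak of the band-passed bipolar EOG within the paced maximal-HOV
#' calibration windows.  Online detection emits an event at the first
#' sample whose absolute value crosses the threshold; direction follows the
#' sign under the right-positive polarity convention, and a refractory
#' period enforces one saccade per command.
#' @name hov-decoding
NULL

HOV_PEAK_WINDOW <- 2.0  # s, window after a paced cue in which to measure peak

# reduce raw EOG to the band-passed bipolar derivation
prep_eog_channel <- function(recording,
                             spec = eog_filter_spec("offline_zero_phase")) {
  if (length(recording$channel_labels) == 1L) return(recording)
  bandpass(bipolar_eog(recording), spec)
}

new_hov_calibration <- function(threshold, refractory = 1.5,
                                polarity_right_positive = TRUE,
                                mean_peak = NA_real_) {
  stopifnot(threshold > 0, refractory >= 0)
  structure(list(threshold = threshold, refractory = refractory,
                 polarity_right_positive = polarity_right_positive,
                 mean_peak = mean_peak),
            class = "hov_calibration")
}

#' @export
print.hov_calibration <- function(x, ...) {
  cat(sprintf("<hov_calibration> threshold %.1f uV (70%% of mean max %.1f uV), refractory %.1f s\n",
              x$threshold, x$mean_peak, x$refractory))
  invisible(x)
}

#' Calibrate HOV detection from paced maximal oculoversions
#'
#' The threshold is set to 70% of the mean absolute peak of the
#' band-passed bipolar signal within each paced-movement window.
#'
#' @param recording calibration EOG ([signal_recording()]) with paced
#'   `hov_left`/`hov_right` annotations; multichannel input is reduced to
#'   the band-passed bipolar derivation.
#' @param fraction threshold fraction of the mean maximal deflection
#'   (study protocol: 0.70).
#' @param refractory minimum time between detected events, seconds.  The
#'   default (1.5 s) exceeds the whole saccade-and-return deflection so
#'   that the high-pass undershoot of the return edge is not read as an
#'   opposite-direction oculoversion.
#' @return A frozen `hov_calibration`.
#' @export
hov_calibrate <- function(recording, fraction = 0.70, refractory = 1.5) {
  x <- prep_eog_channel(recording)
  ann <- x$annotations
  paced <- ann[grepl("^hov_(left|right)$", ann$label), , drop = FALSE]
  if (!nrow(paced))
    stop("no paced hov_left/hov_right annotations in recording")
  sig <- x$samples[1L, ]
  peaks <- vapply(paced$time, function(t0) {
    idx <- sample_window(x, t0, t0 + HOV_PEAK_WINDOW)
    max(abs(sig[idx]))
  }, numeric(1))
  mp <- mean(peaks)
  if (mp <= 0) stop("no measurable HOV peaks in calibration recording")
  new_hov_calibration(fraction * mp, refractory = refractory,
                      mean_peak = mp)
}

#' Detect horizontal oculoversions online
#'
#' @param stream single-channel bipolar EOG ([signal_recording()] or
#'   numeric vector of samples).
#' @param cal a frozen `hov_calibration`.
#' @param fs sampling rate if `stream` is a bare vector.
#' @return Data frame of events with columns `time` (s, first
#'   threshold-crossing sample), `direction` (`"left"`/`"right"`) and
#'   `peak_amplitude` (signed microvolts within 0.5 s of the crossing);
#'   zero rows if none.
#' @export
hov_detect <- function(stream, cal, fs = 1000) {
  stopifnot(inherits(cal, "hov_calibration"))
  if (inherits(stream, "signal_recording")) {
    fs <- stream$fs
    sig <- stream$samples[1L, ]
  } else sig <- as.numeric(stream)
  over <- which(abs(sig) >= cal$threshold)
  events <- list()
  last <- -Inf
  refr_samp <- cal$refractory * fs
  for (i in over) {
    if (i - last < refr_samp) next
    last <- i
    seg <- sig[i:min(length(sig), i + round(0.5 * fs))]
    pk <- seg[which.max(abs(seg))]
    dir <- if ((pk > 0) == cal$polarity_right_positive) "right" else "left"
    events[[length(events) + 1L]] <-
      data.frame(time = (i - 1L) / fs, direction = dir, peak_amplitude = pk)
  }
  if (!length(events))
    return(data.frame(time = numeric(0), direction = character(0),
                      peak_amplitude = numeric(0)))
  do.call(rbind, events)
}

#' @export
#' @rdname hov_calibrate
#' @param object a `hov_calibration`.
#' @param newdata recording or numeric stream to decode.
#' @param ... passed to [hov_detect()].
predict.hov_calibration <- function(object, newdata, ...) {
  if (inherits(newdata, "signal_recording") &&
      length(newdata$channel_labels) > 1L)
    newdata <- prep_eog_channel(newdata)
  hov_detect(newdata, object, ...)
}
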