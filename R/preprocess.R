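#' Band-pass filter specification
#'
#' Butterworth band-pass, realised as a cascade of a high-pass and a
#' low-pass section of `order` poles each (numerically better conditioned
#' than a single band-pass design when the low edge sits far below the
#' Nyquist frequency, as 0.1 Hz does at 1 kHz).  `offline_zero_phase`
#' applies each section forward-backward (no group delay, squared
#' magnitude response); `online_causal` applies them forward only, as the
#' online system must.
#'
#' @param low_cut,high_cut band edges in Hz.
#' @param order Butterworth order of each section, default 4.
#' @param mode `"offline_zero_phase"` or `"online_causal"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut, high_cut, order = 4L,
                        mode = c("offline_zero_phase", "online_causal")) {
  mode <- match.arg(mode)
  stopifnot(low_cut >= 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), mode = mode),
            class = "filter_spec")
}

#' Standard EEG band-pass specification (0.1-30 Hz)
#' @param mode filtering mode, see [filter_spec()].
#' @return A `filter_spec`.
#' @export
eeg_filter_spec <- function(mode = "offline_zero_phase")
  filter_spec(0.1, 30, 4L, mode)

#' Standard EOG band-pass specification (0.1-5 Hz)
#' @param mode filtering mode, see [filter_spec()].
#' @return A `filter_spec`.
#' @export
eog_filter_spec <- function(mode = "offline_zero_phase")
  filter_spec(0.1, 5, 4L, mode)

#' Band-pass filter a recording
#'
#' @param recording a [signal_recording()].
#' @param spec a [filter_spec()].
#' @return A filtered copy of `recording`; annotations preserved.
#' @export
bandpass <- function(recording, spec) {
  stopifnot(inherits(recording, "signal_recording"),
            inherits(spec, "filter_spec"))
  nyq <- recording$fs / 2
  if (spec$high_cut >= nyq)
    stop("high_cut (", spec$high_cut, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  hp <- signal::butter(spec$order, spec$low_cut / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$high_cut / nyq, type = "low")
  apply_sec <- if (spec$mode == "offline_zero_phase") {
    function(x, flt) signal::filtfilt(flt, x)
  } else {
    function(x, flt) as.numeric(signal::filter(flt, x))
  }
  out <- recording
  for (i in seq_len(nrow(out$samples))) {
    x <- out$samples[i, ]
    if (spec$low_cut > 0) x <- apply_sec(x, hp)
    out$samples[i, ] <- apply_sec(x, lp)
  }
  out
}

#' Surface Laplacian derivation
#'
#' Hjorth-style small Laplacian: the center channel minus the mean of its
#' neighbours, sample-wise.  Removes signal components common to all sites.
#'
#' @param recording a [signal_recording()].
#' @param center center channel label (default `"C3"`).
#' @param neighbors neighbour channel labels (default the four remaining
#'   recorded sites F3, T3, Cz, P3).
#' @return A single-channel [signal_recording()] labelled
#'   `"<center>-lap"`; annotations preserved.
#' @export
laplacian <- function(recording, center = "C3",
                      neighbors = c("F3", "T3", "Cz", "P3")) {
  stopifnot(inherits(recording, "signal_recording"))
  missing <- setdiff(c(center, neighbors), recording$channel_labels)
  if (length(missing))
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  nb <- recording$samples[neighbors, , drop = FALSE]
  out <- channel(recording, center) - colMeans(nb)
  signal_recording(matrix(out, nrow = 1L), recording$fs,
                   paste0(center, "-lap"), recording$annotations)
}

#' Bipolar EOG derivation
#'
#' Computes EOGR - EOGL; under the fixed polarity convention positive
#' values denote rightward gaze.
#'
#' @param recording a [signal_recording()] with channels `EOGL`, `EOGR`.
#' @return A single-channel [signal_recording()] labelled `"EOG-bipolar"`.
#' @export
bipolar_eog <- function(recording) {
  stopifnot(inherits(recording, "signal_recording"))
  missing <- setdiff(c("EOGL", "EOGR"), recording$channel_labels)
  if (length(missing))
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  out <- channel(recording, "EOGR") - channel(recording, "EOGL")
  signal_recording(matrix(out, nrow = 1L), recording$fs,
                   "EOG-bipolar", recording$annotations)
}
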