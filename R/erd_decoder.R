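#' @title SMR-ERD decoding
#' @description
#' Calibration and online detection of sensorimotor-rhythm event-related
#' desynchronization (SMR-ERD).  Band power is estimated from an
#' autoregressive model of order 100 fitted with the Burg algorithm
#' (`stats::ar.burg`); the AR power spectral density is evaluated on a
#' 0.1 Hz grid and integrated over the frequencies of interest (FOI,
#' individually selected center frequency +/- 1.5 Hz) by the trapezoidal
#' rule.  ERD is expressed with the power method as the percent change of
#' band power relative to a resting reference value (RV): negative values
#' denote desynchronization.
#' @name erd-decoding
NULL

SPECTRAL_GRID_STEP <- 0.1  # Hz, PSD evaluation grid
SEGMENT_MARGIN <- 0.25     # s, guard band around rest/imagery segment edges

# ---- Burg AR spectral estimation --------------------------------------

burg_fit <- function(window, ar_order) {
  if (stats::sd(window) == 0) return(NULL)
  fit <- .burg_fit_cpp(window, as.integer(ar_order))
  list(ar = fit$ar, var = max(fit$var_prod, 0))
}

# one-sided AR PSD (uV^2/Hz) on `freqs`; E is the precomputed exp matrix
burg_psd_eval <- function(fit, fs, freqs,
                          E = exp(-2i * pi * outer(freqs, seq_along(fit$ar)) / fs)) {
  if (is.null(fit)) return(numeric(length(freqs)))
  denom <- Mod(1 - as.vector(E %*% fit$ar))^2
  2 * fit$var / (fs * denom)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# Adaptive trapezoidal integration of an AR PSD over [band[1], band[2]],
# starting from the 0.1 Hz grid and bisecting intervals until the local
# trapezoid estimate converges.  High-order AR spectra of near-sinusoidal
# signals have resonances far narrower than any fixed grid; the adaptive
# refinement resolves them so a spectral line integrates to (nearly) the
# rhythm's full power.  Work is bounded: each sweep refines at most
# `max_active` segments (those with the largest absolute trapezoid error),
# so the cost per window is deterministic even for pathological
# noise-free inputs whose resonances are arbitrarily narrow.
ar_band_power <- function(fit, fs, band, rtol = 1e-3, max_sweeps = 60L,
                          max_active = 256L) {
  if (is.null(fit)) return(0)
  .ar_band_power_cpp(fit$ar, fit$var, fs, band[1], band[2],
                     SPECTRAL_GRID_STEP, rtol, as.integer(max_sweeps),
                     as.integer(max_active))
}

#' Burg autoregressive band power of one analysis window
#'
#' Fits an AR model of order `ar_order` by the Burg algorithm and returns
#' the integral of its one-sided power spectral density over `band`
#' (trapezoidal rule on a 0.1 Hz grid).
#'
#' @param window numeric vector of samples (length must exceed `ar_order`).
#' @param fs sampling rate in Hz.
#' @param ar_order autoregressive model order (study protocol: 100).
#' @param band numeric length-2, band edges in Hz inside (0, fs/2).
#' @return Nonnegative band power in microvolt^2.
#' @export
burg_band_power <- function(window, fs, ar_order = 100L, band) {
  if (length(window) <= ar_order)
    stop("window (", length(window), " samples) must be longer than ",
         "ar_order (", ar_order, ")")
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            band[2] < fs / 2)
  ar_band_power(burg_fit(window, ar_order), fs, band)
}

band_grid <- function(band) {
  freqs <- seq(band[1], band[2], by = SPECTRAL_GRID_STEP)
  if (freqs[length(freqs)] < band[2]) freqs <- c(freqs, band[2])
  freqs
}

# fit all windows (start indices, common length) of a numeric vector
burg_fit_windows <- function(x, starts, wlen, ar_order) {
  lapply(starts, function(s) burg_fit(x[s:(s + wlen - 1L)], ar_order))
}

# PSD matrix (windows x freqs) from a list of fits
psd_track <- function(fits, fs, freqs) {
  nonnull <- which(!vapply(fits, is.null, logical(1)))
  if (!length(nonnull))
    return(matrix(0, nrow = length(fits), ncol = length(freqs)))
  p <- length(fits[[nonnull[1]]]$ar)
  E <- exp(-2i * pi * outer(freqs, seq_len(p)) / fs)
  t(vapply(fits, burg_psd_eval, numeric(length(freqs)),
           fs = fs, freqs = freqs, E = E))
}

# sliding-window start indices; window timestamp = window end (causal)
sliding_starts <- function(n, wlen, step_samp) {
  if (n < wlen) return(integer(0))
  seq(1L, n - wlen + 1L, by = step_samp)
}

# start indices of windows fully inside [onset, offset] segments
segment_starts <- function(segments, fs, wlen, step_samp, n,
                           margin = SEGMENT_MARGIN) {
  out <- integer(0)
  for (k in seq_len(nrow(segments))) {
    i0 <- floor((segments$onset[k] + margin) * fs) + 1L
    i1 <- ceiling((segments$offset[k] - margin) * fs)
    i1 <- min(i1, n)
    if (i1 - i0 + 1L < wlen) next
    out <- c(out, seq(i0, i1 - wlen + 1L, by = step_samp))
  }
  out
}

# imagery / rest segments from calibration annotations
imagery_segments <- function(recording) {
  ann <- recording$annotations
  on <- ann$time[ann$label == "imagery_start"]
  off <- ann$time[ann$label == "imagery_end"]
  if (!length(on) || length(on) != length(off))
    stop("recording has no paired imagery_start/imagery_end annotations")
  data.frame(onset = sort(on), offset = sort(off))
}

rest_segments <- function(recording) {
  seg <- imagery_segments(recording)
  data.frame(onset = seg$offset,
             offset = c(seg$onset[-1L], duration(recording)))
}

# Band-pass used on the ERD derivation before Burg fitting: gentle order-2
# sections.  A steeper low-pass leaves the 1 kHz signal so close to
# band-limited that the order-100 AR fit becomes near-deterministic
# (prediction variance at numerical zero, degenerate spectrum); the softer
# roll-off keeps enough broadband floor to condition the recursion.
erd_prep_spec <- function(mode = "offline_zero_phase")
  filter_spec(0.1, 30, 2L, mode)

# reduce a raw recording to the single ERD derivation:
# Laplacian-filtered, band-passed C3 (pass-through if already one channel)
prep_erd_channel <- function(recording, spec = erd_prep_spec()) {
  if (length(recording$channel_labels) == 1L) return(recording)
  bandpass(laplacian(recording), spec)
}

# ---- Calibration object -----------------------------------------------

new_erd_calibration <- function(center_freq, rv = NA_real_,
                                threshold = NA_real_, foi_halfwidth = 1.5,
                                ar_order = 100L, window_len = 0.5,
                                step = 0.04, dwell = 0.2, fs = 1000,
                                degenerate = FALSE) {
  stopifnot(foi_halfwidth > 0, ar_order >= 2,
            window_len * fs > ar_order)
  structure(list(center_freq = center_freq, foi_halfwidth = foi_halfwidth,
                 rv = rv, threshold = threshold, ar_order = as.integer(ar_order),
                 window_len = window_len, step = step, dwell = dwell,
                 fs = fs, degenerate = degenerate),
            class = "erd_calibration")
}

foi_band <- function(cal) c(cal$center_freq - cal$foi_halfwidth,
                            cal$center_freq + cal$foi_halfwidth)

#' @export
print.erd_calibration <- function(x, ...) {
  cat("<erd_calibration>\n")
  cat(sprintf("  FOI: %.1f +/- %.1f Hz   AR order: %d   window %.0f ms / step %.0f ms\n",
              x$center_freq, x$foi_halfwidth, x$ar_order,
              1000 * x$window_len, 1000 * x$step))
  cat(sprintf("  RV: %.3f uV^2   threshold: %.1f %%ERD   dwell: %.0f ms%s\n",
              x$rv, x$threshold, 1000 * x$dwell,
              if (isTRUE(x$degenerate)) "   [DEGENERATE: no ERD contrast]" else ""))
  invisible(x)
}

#' Nominal online detection latency of a calibrated ERD decoder
#'
#' Half the analysis window (the time for an ERD onset to dominate the
#' causal window) plus the dwell (debounce) time.
#'
#' @param cal an `erd_calibration`.
#' @return Latency in seconds.
#' @export
erd_detection_latency <- function(cal) cal$window_len / 2 + cal$dwell

# ---- Calibration operations -------------------------------------------

#' Select the subject-specific SMR center frequency
#'
#' Scans candidate center frequencies over `search_band` and returns the
#' one with the strongest rest-vs-imagery desynchronization.  The contrast
#' is evaluated in a narrow `+/- contrast_halfwidth` window around each
#' candidate: against a 1/f background, a contrast over the full +/- 1.5 Hz
#' FOI band is biased toward placing the rhythm at the band edge (less
#' background in the upper half), whereas the narrow window localizes the
#' desynchronizing peak itself.
#'
#' @param recording calibration EEG ([signal_recording()]) with
#'   `imagery_start`/`imagery_end` annotations; multichannel input is
#'   reduced to the Laplacian C3 derivation.
#' @param search_band numeric length-2 search range in Hz (default 8-13).
#' @param foi_halfwidth half-width of the frequencies of interest, Hz
#'   (kept for the degenerate-contrast check on the selected candidate).
#' @param ar_order,window_len Burg model order and analysis window (s).
#' @param grid candidate spacing in Hz.
#' @param contrast_halfwidth half-width in Hz of the contrast window used
#'   to score candidates.
#' @return Selected center frequency in Hz, with attribute `erd_contrast`
#'   (the achieved mean ERD percent).  If no candidate attains an ERD
#'   contrast below -5%, the selection is flagged degenerate with a warning
#'   and attribute `degenerate = TRUE`.
#' @export
select_center_freq <- function(recording, search_band = c(8, 13),
                               foi_halfwidth = 1.5, ar_order = 100L,
                               window_len = 0.5, grid = 0.5,
                               contrast_halfwidth = 0.5) {
  x <- prep_erd_channel(recording)
  sig <- x$samples[1L, ]
  fs <- x$fs
  wlen <- round(window_len * fs)
  seg_im <- imagery_segments(x)
  seg_rest <- rest_segments(x)
  st_im <- segment_starts(seg_im, fs, wlen, wlen, length(sig))
  st_rest <- segment_starts(seg_rest, fs, wlen, wlen, length(sig))
  if (!length(st_im) || !length(st_rest))
    stop("no usable imagery/rest windows in recording")
  cand <- seq(search_band[1], search_band[2], by = grid)
  freqs <- band_grid(c(min(cand) - foi_halfwidth, max(cand) + foi_halfwidth))
  psd_im <- psd_track(burg_fit_windows(sig, st_im, wlen, ar_order), fs, freqs)
  psd_rest <- psd_track(burg_fit_windows(sig, st_rest, wlen, ar_order), fs, freqs)
  band_contrast <- function(f0, hw) {
    sel <- freqs >= f0 - hw - 1e-9 & freqs <= f0 + hw + 1e-9
    p_im <- mean(apply(psd_im[, sel, drop = FALSE], 1L,
                       function(y) trapz(freqs[sel], y)))
    p_rest <- mean(apply(psd_rest[, sel, drop = FALSE], 1L,
                         function(y) trapz(freqs[sel], y)))
    (p_im - p_rest) / p_rest * 100
  }
  contrast <- vapply(cand, band_contrast, numeric(1), hw = contrast_halfwidth)
  best <- which.min(contrast)
  out <- cand[best]
  foi_contrast <- band_contrast(cand[best], foi_halfwidth)
  attr(out, "erd_contrast") <- foi_contrast
  if (foi_contrast > -5) {
    warning("no reliable ERD contrast in search band (best FOI contrast ",
            round(foi_contrast, 1), "%); selection is degenerate")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Reference band power (RV) from resting segments
#'
#' Mean FOI band power over all rest (inter-trial interval) windows of a
#' calibration recording.
#'
#' @param recording calibration EEG with imagery annotations (rest = the
#'   intervals between imagery trials); multichannel input is reduced to
#'   the Laplacian C3 derivation.
#' @param cal an `erd_calibration` (draft) carrying the FOI and window
#'   parameters.
#' @return RV in microvolt^2.
#' @export
compute_rv <- function(recording, cal) {
  x <- prep_erd_channel(recording)
  sig <- x$samples[1L, ]
  wlen <- round(cal$window_len * x$fs)
  st <- segment_starts(rest_segments(x), x$fs, wlen, wlen, length(sig))
  if (!length(st)) stop("no usable rest segments in recording")
  fits <- burg_fit_windows(sig, st, wlen, cal$ar_order)
  mean(vapply(fits, ar_band_power, numeric(1), fs = x$fs,
              band = foi_band(cal)))
}

#' ERD percent time course of a single-channel signal
#'
#' Sliding-window band power converted to ERD percent with the power
#' method: `(band_power - rv) / rv * 100`.  Window timestamps are causal
#' (the time of the last sample in each window).
#'
#' @param signal single-channel [signal_recording()] or numeric vector.
#' @param cal a frozen `erd_calibration` (`rv` and `center_freq` set).
#' @param step window step in seconds (defaults to `cal$step`).
#' @param fs sampling rate, required if `signal` is a bare vector.
#' @return An `erd_timecourse`: data frame with columns `times`,
#'   `erd_percent`, `active` (`erd_percent <= threshold`).
#' @export
erd_timecourse <- function(signal, cal, step = cal$step, fs = cal$fs) {
  if (inherits(signal, "signal_recording")) {
    fs <- signal$fs
    sig <- signal$samples[1L, ]
  } else sig <- as.numeric(signal)
  if (!is.finite(cal$rv) || cal$rv <= 0)
    stop("calibration has no positive reference value (rv)")
  wlen <- round(cal$window_len * fs)
  st <- sliding_starts(length(sig), wlen, max(1L, round(step * fs)))
  if (!length(st)) stop("signal shorter than one analysis window")
  fits <- burg_fit_windows(sig, st, wlen, cal$ar_order)
  bp <- vapply(fits, ar_band_power, numeric(1), fs = fs,
               band = foi_band(cal))
  erd <- (bp - cal$rv) / cal$rv * 100
  thr <- if (is.finite(cal$threshold)) cal$threshold else -Inf
  out <- data.frame(times = (st - 1L + wlen) / fs, erd_percent = erd,
                    active = erd <= thr)
  class(out) <- c("erd_timecourse", "data.frame")
  attr(out, "calibration") <- cal
  out
}

#' @export
plot.erd_timecourse <- function(x, ...) {
  graphics::plot(x$times, x$erd_percent, type = "l",
                 xlab = "time (s)", ylab = "ERD (%)", ...)
  cal <- attr(x, "calibration")
  if (!is.null(cal) && is.finite(cal$threshold))
    graphics::abline(h = cal$threshold, lty = 2)
  invisible(x)
}

#' Detection threshold from per-trial mean elicited ERD
#'
#' The detection threshold is the average of the elicited SMR-ERD across
#' all trials: the mean over imagery epochs of the mean ERD percent of the
#' windows inside each epoch.
#'
#' @param timecourse an `erd_timecourse` of the feedback calibration run.
#' @param epochs data frame with columns `onset`, `offset` (seconds), one
#'   row per imagery trial.
#' @return Threshold in ERD percent (negative for desynchronization).
#' @export
erd_threshold <- function(timecourse, epochs) {
  if (nrow(epochs) == 0L) stop("no imagery trials supplied")
  # only windows fully inside the epoch (window timestamps are causal, so
  # a window ending just after onset still covers mostly pre-onset rest)
  cal <- attr(timecourse, "calibration")
  lead <- if (!is.null(cal)) cal$window_len + SEGMENT_MARGIN else 0
  per_trial <- vapply(seq_len(nrow(epochs)), function(k) {
    sel <- timecourse$times >= epochs$onset[k] + lead &
      timecourse$times <= epochs$offset[k]
    if (!any(sel)) return(NA_real_)
    mean(timecourse$erd_percent[sel])
  }, numeric(1))
  if (all(is.na(per_trial))) stop("no analysis windows inside any trial")
  mean(per_trial, na.rm = TRUE)
}

#' Calibrate the full SMR-ERD decoder
#'
#' Runs the complete calibration chain on annotated recordings: selects
#' the subject-specific center frequency, computes the resting reference
#' value (RV) over the first run's inter-trial intervals, and sets the
#' detection threshold to the average elicited ERD across the feedback
#' run's imagery trials.
#'
#' @param rv_run calibration EEG recording for center-frequency selection
#'   and RV (imagery-annotated).
#' @param feedback_run feedback-run EEG recording for the threshold;
#'   defaults to `rv_run`.
#' @param search_band center-frequency search range in Hz.
#' @param foi_halfwidth,ar_order,window_len,step,dwell decoder parameters;
#'   see [erd_timecourse()] and [detect_erd_online()].
#' @param center_freq optional fixed center frequency (skips selection).
#' @return A frozen `erd_calibration`; flagged degenerate (with a warning)
#'   if the calibrated threshold shows no usable ERD contrast (> -5%).
#' @export
erd_calibrate <- function(rv_run, feedback_run = rv_run,
                          search_band = c(8, 13), foi_halfwidth = 1.5,
                          ar_order = 100L, window_len = 0.5, step = 0.04,
                          dwell = 0.2, center_freq = NULL) {
  if (is.null(center_freq)) {
    center_freq <- suppressWarnings(
      select_center_freq(rv_run, search_band, foi_halfwidth, ar_order,
                         window_len))
  }
  cal <- new_erd_calibration(as.numeric(center_freq),
                             foi_halfwidth = foi_halfwidth,
                             ar_order = ar_order, window_len = window_len,
                             step = step, dwell = dwell,
                             fs = rv_run$fs)
  cal$rv <- compute_rv(rv_run, cal)
  fb <- prep_erd_channel(feedback_run)
  tc <- erd_timecourse(fb, cal, step = window_len)
  cal$threshold <- erd_threshold(tc, imagery_segments(fb))
  if (cal$threshold > -5) {
    cal$degenerate <- TRUE
    warning("calibrated threshold ", round(cal$threshold, 1),
            "% shows no usable ERD contrast; calibration is non-informative")
  }
  cal
}

#' Online ERD activation detection
#'
#' Streams the ERD time course and opens an activation when the ERD
#' percent stays at or below the calibrated threshold for at least `dwell`
#' seconds; the activation closes when it rises above the threshold.
#' Reported onsets are the threshold-crossing times (the dwell only gates
#' whether a crossing counts).
#'
#' @param stream single-channel [signal_recording()] or numeric vector of
#'   the preprocessed ERD derivation.
#' @param cal a frozen `erd_calibration`.
#' @param dwell debounce time in seconds (defaults to `cal$dwell`).
#' @param fs sampling rate if `stream` is a bare vector.
#' @return Data frame of non-overlapping activation intervals with columns
#'   `onset`, `offset` (seconds); zero rows if none.
#' @export
detect_erd_online <- function(stream, cal, dwell = cal$dwell, fs = cal$fs) {
  stopifnot(dwell >= 0)
  tc <- erd_timecourse(stream, cal, fs = fs)
  activation_intervals(tc, dwell)
}

# runs of active windows lasting >= dwell
activation_intervals <- function(tc, dwell) {
  act <- tc$active
  if (!any(act)) return(data.frame(onset = numeric(0), offset = numeric(0)))
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values &
    (tc$times[ends] - tc$times[starts]) >= dwell - 1e-9
  data.frame(onset = tc$times[starts[keep]], offset = tc$times[ends[keep]])
}

#' @export
#' @rdname erd_calibrate
#' @param object an `erd_calibration`.
#' @param newdata recording or numeric stream to decode.
#' @param type `"timecourse"` or `"activations"`.
#' @param ... passed to [erd_timecourse()] / [detect_erd_online()].
predict.erd_calibration <- function(object, newdata,
                                    type = c("timecourse", "activations"),
                                    ...) {
  type <- match.arg(type)
  if (inherits(newdata, "signal_recording") &&
      length(newdata$channel_labels) > 1L)
    newdata <- prep_erd_channel(newdata)
  switch(type,
         timecourse = erd_timecourse(newdata, object, ...),
         activations = detect_erd_online(newdata, object, ...))
}
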