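#' Normalized hand open/close time
#'
#' Elapsed opening/closing time normalized to the device's mechanism time
#' (the "ERD duration"): `(t_elapsed - erd_duration) / erd_duration`.
#' 0 means the motion took exactly the mechanism time (uninterrupted ERD);
#' positive values measure how much pauses stretched it.
#'
#' @param t_elapsed seconds between the beginning and the end of the
#'   opening/closing movement.
#' @param erd_duration the mechanism's full open/close time (1.5 s hand
#'   exoskeleton, 1.2 s gripper).
#' @return Dimensionless fraction (multiply by 100 for percent).
#' @export
open_close_norm <- function(t_elapsed, erd_duration) {
  if (any(erd_duration <= 0)) stop("erd_duration must be positive")
  if (any(t_elapsed <= 0)) stop("t_elapsed must be positive")
  (t_elapsed - erd_duration) / erd_duration
}

#' Time to initialize (TTI) or pre-cue activation time (Pre-TTI)
#'
#' TTI is the time from the cue to the first decoder activation onset after
#' it.  If the decoder is already active at the cue, or an activation onset
#' precedes the cue within the sub-task window, the (negative) Pre-TTI is
#' the time back to the last such onset.  Exactly one of the two exists for
#' a successful initialization; if no activation occurs before `window_end`
#' the sub-task is unsuccessful and contributes no timing value.
#'
#' @param cue_time cue presentation time in seconds.
#' @param activations data frame of activation intervals (`onset`,
#'   `offset`); point events may use `offset = onset`.
#' @param window_end end of the sub-task window in seconds.
#' @param window_start start of the sub-task window (the previous
#'   sub-task's completion); earlier activations are out of window unless
#'   still open at the cue.
#' @return List with elements `tti`, `pre_tti`, `tti_plus_pre_tti`
#'   (numeric or `NA`) and `success` (logical).
#' @export
tti_or_pre_tti <- function(cue_time, activations, window_end,
                           window_start = -Inf) {
  a <- activations
  in_window <- a$onset >= window_start & a$onset <= window_end
  open_at_cue <- a$onset <= cue_time & a$offset >= cue_time
  prior <- a$onset[(in_window | open_at_cue) & a$onset <= cue_time]
  res <- list(tti = NA_real_, pre_tti = NA_real_,
              tti_plus_pre_tti = NA_real_, success = FALSE)
  if (length(prior)) {
    res$pre_tti <- max(prior) - cue_time
    res$tti_plus_pre_tti <- res$pre_tti
    res$success <- TRUE
    return(res)
  }
  after <- a$onset[in_window & a$onset > cue_time]
  if (length(after)) {
    res$tti <- min(after) - cue_time
    res$tti_plus_pre_tti <- res$tti
    res$success <- TRUE
  }
  res
}

SUBTASK_MODALITY <- c(s1 = "gaze", s2 = "hov", s3 = "erd",
                      s4 = "hov", s5 = "erd")
SUBTASK_COMPLETION <- c(s1 = "confirm", s2 = "reach", s3 = "grasp",
                        s4 = "place", s5 = "release")

#' Per-trial feasibility metrics from a task log
#'
#' Extracts, for every repetition and sub-task, the TTI or Pre-TTI of the
#' matching modality (gaze for selection, HOV for reach/place, ERD for
#' grasp/release) and, for the grasp/release sub-tasks, the normalized
#' open/close time.
#'
#' @param log a `task_log` from [run_session()].
#' @param device the [device_model()] used in the session.
#' @return Data frame with one row per repetition x sub-task: columns
#'   `rep`, `subtask`, `modality`, `cue`, `success`, `tti`, `pre_tti`,
#'   `tti_plus_pre_tti`, `open_close_norm`.
#' @export
trial_metrics <- function(log, device) {
  stopifnot(inherits(log, "data.frame"))
  erd_acts <- data.frame(
    onset = log$time[log$event == "erd_on"],
    offset = log$time[log$event == "erd_off"])
  hov_t <- log$time[log$event == "hov" & grepl("^right", log$detail)]
  hov_acts <- data.frame(onset = hov_t, offset = hov_t)
  gaze_t <- log$time[log$event == "gaze_select"]
  gaze_acts <- data.frame(onset = gaze_t, offset = gaze_t)
  acts_of <- list(gaze = gaze_acts, hov = hov_acts, erd = erd_acts)

  cues <- log[log$event == "cue_issued", , drop = FALSE]
  session_end <- max(log$time)
  rows <- list()
  for (k in seq_len(nrow(cues))) {
    r <- cues$rep[k]
    sub <- cues$detail[k]
    modality <- SUBTASK_MODALITY[[sub]]
    # window: from this cue's state context to the sub-task's completion
    # (or, if it never completed, the end of the session)
    comp <- subtask_completion_time(log, r, sub)
    window_end <- if (is.na(comp)) session_end else comp
    window_start <- subtask_window_start(log, r, sub)
    tm <- tti_or_pre_tti(cues$time[k], acts_of[[modality]], window_end,
                         window_start)
    ocn <- NA_real_
    if (sub %in% c("s3", "s5") && !is.na(comp)) {
      start <- hand_motion_start(log, r, sub)
      if (!is.na(start))
        ocn <- open_close_norm(comp - start, device$erd_duration)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      rep = r, subtask = sub, modality = modality, cue = cues$time[k],
      success = tm$success && !is.na(comp), tti = tm$tti,
      pre_tti = tm$pre_tti, tti_plus_pre_tti = tm$tti_plus_pre_tti,
      open_close_norm = ocn, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$rep, out$subtask), ]
}

subtask_completion_time <- function(log, r, sub) {
  if (sub == "s1") {
    t <- log$time[log$event == "state_enter" & log$state == "S2" &
                    log$rep == r]
  } else {
    key <- SUBTASK_COMPLETION[[sub]]
    t <- log$time[log$event == "motion_complete" & log$rep == r &
                    grepl(paste0("^", key), log$detail)]
  }
  if (length(t)) t[1] else NA_real_
}

subtask_window_start <- function(log, r, sub) {
  state <- c(s1 = "S1", s2 = "S2", s3 = "S3", s4 = "S4", s5 = "S5")[[sub]]
  t <- log$time[log$event == "state_enter" & log$state == state &
                  log$rep == r]
  if (length(t)) t[1] else 0
}

hand_motion_start <- function(log, r, sub) {
  key <- if (sub == "s3") "grasp" else "release"
  t <- log$time[log$event == "motion_start" & log$rep == r &
                  log$detail == key]
  if (length(t)) t[1] else NA_real_
}

#' Condition-level summary: fluency and reliability
#'
#' Median and interquartile range of the pooled TTI+Pre-TTI values of one
#' condition (device x mode), with the study's feasibility verdicts:
#' fluent control if the median is below `fluent_cut` (3 s), reliable
#' control if the 75th percentile is below `reliable_cut` (5 s).
#' Quantiles use linear interpolation between order statistics.
#'
#' @param values numeric vector of TTI+Pre-TTI values (seconds) of the
#'   successful initializations, or a data frame from [trial_metrics()].
#' @param fluent_cut,reliable_cut verdict cutoffs in seconds.
#' @param n_total optional total number of attempted sub-task
#'   initializations (to report the success rate alongside).
#' @return An object of class `condition_summary`: list with `median`,
#'   `q25`, `q75`, `fluent`, `reliable`, `n_trials`, `n_total`,
#'   `success_rate`.
#' @export
summarize_condition <- function(values, fluent_cut = 3, reliable_cut = 5,
                                n_total = NULL) {
  if (is.data.frame(values)) {
    if (is.null(n_total)) n_total <- nrow(values)
    values <- values$tti_plus_pre_tti[values$success]
  }
  values <- values[!is.na(values)]
  if (!length(values)) stop("no successful timing values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 fluent = q[2] < fluent_cut, reliable = q[3] < reliable_cut,
                 n_trials = length(values),
                 n_total = n_total %||% length(values),
                 success_rate = length(values) / (n_total %||% length(values))),
            class = "condition_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> median %.2f s [%.2f, %.2f] (n=%d/%d)\n",
              x$median, x$q25, x$q75, x$n_trials, x$n_total))
  cat(sprintf("  fluent (<3 s median): %s   reliable (<5 s q75): %s\n",
              x$fluent, x$reliable))
  invisible(x)
}
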