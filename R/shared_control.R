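#' Device timing model
#'
#' Represents an assistive device purely by its timing constants: the
#' cumulative commanded-motion time to fully open/close the hand mechanism
#' (`erd_duration`: 1.5 s for the hand exoskeleton, 1.2 s for the gripper
#' of the external manipulator) and the durations of the automatic motion
#' segments (reach, transport to mouth/glass, return).  `select_confirm`
#' is the confirmation window after a gaze selection during which a left
#' HOV vetoes the selection.
#'
#' @param name `"exoskeleton"` or `"manipulator"`.
#' @param erd_duration seconds of cumulative commanded motion to fully
#'   open/close; defaults to 1.5 (exoskeleton) or 1.2 (manipulator).
#' @param reach_duration,transport_duration,return_duration seconds of the
#'   automatic motion segments (placeholders; not reported for the real
#'   robots).
#' @param select_confirm seconds of the post-selection veto window.
#' @return An object of class `device_model`.
#' @export
device_model <- function(name = c("exoskeleton", "manipulator"),
                         erd_duration = NULL,
                         reach_duration = 5, transport_duration = 5,
                         return_duration = 5, select_confirm = 1.0) {
  name <- match.arg(name)
  if (is.null(erd_duration))
    erd_duration <- if (name == "exoskeleton") 1.5 else 1.2
  stopifnot(erd_duration > 0, reach_duration > 0,
            transport_duration > 0, return_duration > 0,
            select_confirm > 0)
  structure(list(name = name, erd_duration = erd_duration,
                 reach_duration = reach_duration,
                 transport_duration = transport_duration,
                 return_duration = return_duration,
                 select_confirm = select_confirm),
            class = "device_model")
}

#' @export
print.device_model <- function(x, ...) {
  cat(sprintf("<device_model> %s: open/close %.1f s; reach/transport/return %.1f/%.1f/%.1f s\n",
              x$name, x$erd_duration, x$reach_duration,
              x$transport_duration, x$return_duration))
  invisible(x)
}

FSM_TICK <- 0.01  # s; the supervisor runs at 100 Hz

#' Initial state of the shared-control machine
#'
#' @return A list describing the machine state: `state` (S1..S5), `phase`
#'   (awaiting-input, confirm or automatic-motion sub-phase), hand-motion
#'   progress bookkeeping, the selected object and the repetition counter.
#' @export
fsm_init <- function() {
  list(state = "S1", phase = "await_gaze", selected = NULL,
       confirm_end = NA_real_, auto_end = NA_real_, auto_detail = NA_character_,
       hand_progress = 0, moving = FALSE, rep = 1L)
}

fsm_record <- function(time, event, state, detail, rep) {
  data.frame(time = time, event = event, state = state,
             detail = detail, rep = rep, stringsAsFactors = FALSE)
}

#' Advance the shared-control machine by one 10 ms tick
#'
#' Implements the 5-state supervisor: object selection by gaze with a
#' left-HOV veto (S1), automatic reaching triggered by a right HOV (S2),
#' hand closing commanded while the SMR-ERD signal is below threshold with
#' automatic transport on completion (S3), placing back triggered by a
#' right HOV (S4), and hand opening with automatic return (S5).  Inputs
#' irrelevant to the current state are logged and ignored: concurrent
#' triggering of reach/retract and hand open/close is impossible by
#' construction.
#'
#' @param fsm machine state, from [fsm_init()] or a previous step.
#' @param t current time in seconds (ticks are 10 ms apart).
#' @param input list with optional elements `gaze_id` (character),
#'   `hov` (`"left"`/`"right"`), and `erd_active` (logical, default FALSE).
#' @param device a [device_model()].
#' @param mode `"synchronous"` or `"asynchronous"` (logged only; the
#'   transition rules are mode-independent).
#' @return List with elements `fsm` (updated state) and `records`
#'   (data frame of emitted log records, possibly empty).
#' @export
fsm_step <- function(fsm, t, input = list(), device,
                     mode = "synchronous") {
  if (!is.list(input)) stop("malformed tick input: must be a list")
  erd_active <- isTRUE(input$erd_active)
  hov <- input$hov
  if (!is.null(hov) && !hov %in% c("left", "right"))
    stop("malformed tick input: hov must be 'left' or 'right'")
  recs <- list()
  log <- function(event, detail = "") {
    recs[[length(recs) + 1L]] <<-
      fsm_record(t, event, fsm$state, detail, fsm$rep)
  }
  enter <- function(state, phase) {
    fsm$state <<- state
    fsm$phase <<- phase
    recs[[length(recs) + 1L]] <<-
      fsm_record(t, "state_enter", state, phase, fsm$rep)
  }

  # automatic-motion sub-phases complete on their own
  if (fsm$phase %in% c("auto_reach", "auto_transport", "auto_place",
                       "auto_home") && t >= fsm$auto_end - 1e-9) {
    log("motion_complete", fsm$auto_detail)
    switch(fsm$phase,
           auto_reach = { fsm$hand_progress <- 0; fsm$moving <- FALSE
                          enter("S3", "hand") },
           auto_transport = enter("S4", "await_hov"),
           auto_place = { fsm$hand_progress <- 0; fsm$moving <- FALSE
                          enter("S5", "hand") },
           auto_home = { fsm$rep <- fsm$rep + 1L
                         fsm$selected <- NULL
                         enter("S1", "await_gaze") })
    return(list(fsm = fsm, records = do.call(rbind, recs)))
  }

  if (fsm$phase == "await_gaze") {
    if (!is.null(hov)) log("hov", paste0(hov, ":ignored"))
    if (!is.null(input$gaze_id)) {
      fsm$selected <- input$gaze_id
      fsm$confirm_end <- t + device$select_confirm
      fsm$phase <- "confirm"
      log("gaze_select", input$gaze_id)
    }
  } else if (fsm$phase == "confirm") {
    if (identical(hov, "left")) {
      log("veto", fsm$selected)
      fsm$selected <- NULL
      fsm$phase <- "await_gaze"
    } else if (t >= fsm$confirm_end - 1e-9) {
      enter("S2", "await_hov")
    }
  } else if (fsm$phase == "await_hov") {
    if (identical(hov, "right")) {
      segment <- if (fsm$state == "S2") "reach" else "place"
      dur <- if (fsm$state == "S2") device$reach_duration else
        device$return_duration
      log("hov", hov)
      log("motion_start", segment)
      fsm$phase <- paste0("auto_", segment)
      fsm$auto_detail <- segment
      fsm$auto_end <- t + dur
    } else if (!is.null(hov)) {
      log("hov", paste0(hov, ":ignored"))
    }
  } else if (fsm$phase == "hand") {
    if (!is.null(hov)) log("hov", paste0(hov, ":ignored"))
    hand <- if (fsm$state == "S3") "grasp" else "release"
    if (erd_active) {
      if (!fsm$moving) { log("motion_start", hand); fsm$moving <- TRUE }
      fsm$hand_progress <- fsm$hand_progress + FSM_TICK
      if (fsm$hand_progress >= device$erd_duration - 1e-9) {
        # motion is commanded over [t, t + tick): completion is at tick end,
        # so an uninterrupted close spans exactly erd_duration
        t_done <- t + FSM_TICK
        recs[[length(recs) + 1L]] <- fsm_record(
          t_done, "motion_complete",
          fsm$state, sprintf("%s:commanded=%.2f", hand, fsm$hand_progress),
          fsm$rep)
        fsm$moving <- FALSE
        if (fsm$state == "S3") {
          recs[[length(recs) + 1L]] <- fsm_record(
            t_done, "motion_start", fsm$state, "transport", fsm$rep)
          fsm$phase <- "auto_transport"; fsm$auto_detail <- "transport"
          fsm$auto_end <- t_done + device$transport_duration
        } else {
          recs[[length(recs) + 1L]] <- fsm_record(
            t_done, "motion_start", fsm$state, "home", fsm$rep)
          fsm$phase <- "auto_home"; fsm$auto_detail <- "home"
          fsm$auto_end <- t_done + device$return_duration
        }
      }
    } else if (fsm$moving) {
      log("motion_pause", hand)
      fsm$moving <- FALSE
    }
  } else {  # automatic motion still running: all inputs ignored
    if (!is.null(hov)) log("hov", paste0(hov, ":ignored"))
  }
  list(fsm = fsm,
       records = if (length(recs)) do.call(rbind, recs) else NULL)
}

# subtask awaited in each awaiting phase (for cue bookkeeping)
awaiting_subtask <- function(fsm) {
  if (fsm$phase == "await_gaze") return("s1")
  if (fsm$phase == "await_hov") return(if (fsm$state == "S2") "s2" else "s4")
  if (fsm$phase == "hand" && !fsm$moving && fsm$hand_progress == 0)
    return(if (fsm$state == "S3") "s3" else "s5")
  NA_character_
}

#' Run a full decoded session through the shared-control machine
#'
#' Decodes the session's EEG (causal Laplacian + band-pass, Burg ERD
#' detection) and EOG (causal bipolar band-pass, HOV detection), then
#' drives the 100 Hz supervisor over the whole recording.  Gaze selections
#' are consumed as ready-made object-ID events from the session
#' annotations.  In synchronous mode, `cue_issued` records carry the
#' planned display time of each cue; in asynchronous mode they mark the
#' state-entry time (the reference used by the feasibility metrics).
#'
#' @param eeg,eog [signal_recording()]s of the session.
#' @param annotations session event table (from [generate_task_session()]),
#'   with planned cues and gaze intents.
#' @param erd_cal frozen `erd_calibration`.
#' @param hov_cal frozen `hov_calibration`.
#' @param device a [device_model()].
#' @param mode `"synchronous"` or `"asynchronous"`.
#' @return A `task_log`: data frame of timestamped records (`time`,
#'   `event`, `state`, `detail`, `rep`) including decoder events
#'   (`erd_on`/`erd_off`, `hov`), cues and all FSM transitions.
#' @export
run_session <- function(eeg, eog, annotations, erd_cal, hov_cal,
                        device, mode = c("synchronous", "asynchronous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(erd_cal, "erd_calibration"),
            inherits(hov_cal, "hov_calibration"))
  erd_sig <- bandpass(laplacian(eeg),
                      erd_prep_spec("online_causal"))
  eog_sig <- bandpass(bipolar_eog(eog), eog_filter_spec("online_causal"))
  acts <- detect_erd_online(erd_sig, erd_cal)
  hovs <- hov_detect(eog_sig, hov_cal)
  gaze <- annotations[grepl("^intent:s1:gaze:", annotations$label), ,
                      drop = FALSE]
  gaze$object <- sub("^intent:s1:gaze:", "", gaze$label)
  cues <- annotations[grepl("^cue:s[1-5]$", annotations$label), ,
                      drop = FALSE]
  cues$subtask <- sub("^cue:", "", cues$label)

  n_ticks <- floor(duration(eeg) / FSM_TICK)
  tick_of <- function(tt) pmin(n_ticks, pmax(1L, floor(tt / FSM_TICK) + 1L))
  erd_active <- rep(FALSE, n_ticks)
  for (k in seq_len(nrow(acts)))
    erd_active[tick_of(acts$onset[k]):tick_of(acts$offset[k])] <- TRUE
  hov_at <- rep(NA_character_, n_ticks)
  if (nrow(hovs)) hov_at[tick_of(hovs$time)] <- hovs$direction
  gaze_at <- rep(NA_character_, n_ticks)
  if (nrow(gaze)) gaze_at[tick_of(gaze$time)] <- gaze$object

  fsm <- fsm_init()
  recs <- list(fsm_record(0, "state_enter", "S1", "await_gaze", 1L))
  nrec <- 1L
  push <- function(df) {
    if (is.null(df)) return()
    nrec <<- nrec + 1L
    recs[[nrec]] <<- df
  }
  # decoder events are logged once, independent of FSM state
  for (k in seq_len(nrow(acts))) {
    push(fsm_record(acts$onset[k], "erd_on", "", "", NA_integer_))
    push(fsm_record(acts$offset[k], "erd_off", "", "", NA_integer_))
  }
  max_rep <- if (nrow(cues)) max(cues$trial_index) else 1L
  cued <- character(0)  # "rep:subtask" pairs already cued
  for (i in seq_len(n_ticks)) {
    t <- (i - 1L) * FSM_TICK
    if (fsm$rep > max_rep) break  # all planned repetitions completed
    sub <- awaiting_subtask(fsm)
    if (!is.na(sub)) {
      key <- paste0(fsm$rep, ":", sub)
      if (!key %in% cued) {
        cued <- c(cued, key)
        planned <- cues$time[cues$trial_index == fsm$rep &
                               cues$subtask == sub]
        cue_t <- if (mode == "synchronous" && length(planned))
          max(planned[1], t) else t
        push(fsm_record(cue_t, "cue_issued", fsm$state, sub, fsm$rep))
      }
    }
    input <- list(erd_active = erd_active[i])
    if (!is.na(hov_at[i])) input$hov <- hov_at[i]
    if (!is.na(gaze_at[i])) input$gaze_id <- gaze_at[i]
    st <- fsm_step(fsm, t, input, device, mode)
    fsm <- st$fsm
    push(st$records)
  }
  log <- do.call(rbind, recs[seq_len(nrec)])
  log <- log[order(log$time), ]
  rownames(log) <- NULL
  class(log) <- c("task_log", "data.frame")
  attr(log, "mode") <- mode
  attr(log, "device") <- device$name
  log
}

#' @export
#' @rdname run_session
#' @param session a `task_session` from [generate_task_session()].
run_task_session <- function(session, erd_cal, hov_cal) {
  run_session(session$eeg, session$eog, session$annotations,
              erd_cal, hov_cal, session$device, session$plan$mode)
}
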