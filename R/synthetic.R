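#' @title Synthetic EEG/EOG generation for a hybrid BCI
#' @description
#' Generators for the calibration and task protocols of a hybrid EEG/EOG
#' control interface.  EEG is modelled as an amplitude-modulated sinusoid at
#' the participant's SMR center frequency on channel C3 (attenuated by
#' `erd_depth` during motor-imagery epochs, with 200 ms linear ramps) on top
#' of 1/f-shaped Gaussian background noise; neighbouring channels (F3, T3,
#' Cz, P3) carry background noise plus a common-mode component that the
#' surface Laplacian removes.  EOG oculoversions are smoothed steps (50 ms
#' sigmoid rise, ~1 s hold) of opposite sign on the two canthus electrodes.
#' All generation is bit-reproducible given the profile/plan seeds.
#' @name synthetic
NULL

EEG_CHANNELS <- c("F3", "T3", "C3", "Cz", "P3")
EOG_CHANNELS <- c("EOGL", "EOGR")
ERD_RAMP <- 0.2     # s, linear ERD onset/offset ramp
HOV_RISE <- 0.05    # s, sigmoid rise time of a saccade step
HOV_HOLD <- 1.0     # s, sustained deflection before return

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# 1/f-shaped Gaussian noise of given RMS (flat below 1 Hz), via FFT shaping.
# The transform runs at the next 2-3-5-smooth length (arbitrary session
# lengths otherwise hit the quadratic mixed-radix FFT worst case).
pink_noise <- function(n, fs, rms) {
  if (rms <= 0 || n == 0L) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  f <- seq(0, fs, length.out = m + 1L)[seq_len(m)]
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, 1))                  # 1/sqrt(f) amplitude shaping
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE))[seq_len(n)] / m
  x * rms / stats::sd(x)
}

# amplitude envelope (RMS units): rest level with dips over `epochs`
# (data.frame onset/offset, seconds), linear ramps of ERD_RAMP seconds
erd_envelope <- function(n, fs, rest, imagery, epochs) {
  tt <- (seq_len(n) - 1L) / fs
  env <- rep(rest, n)
  if (is.null(epochs) || nrow(epochs) == 0L) return(env)
  for (k in seq_len(nrow(epochs))) {
    on <- epochs$onset[k]; off <- epochs$offset[k]
    idx <- tt >= on & tt < off
    env[idx] <- imagery
    ron <- tt >= on & tt < on + ERD_RAMP
    env[ron] <- rest + (imagery - rest) * (tt[ron] - on) / ERD_RAMP
    roff <- tt >= off & tt < off + ERD_RAMP
    env[roff] <- imagery + (rest - imagery) * (tt[roff] - off) / ERD_RAMP
  }
  env
}

# build the 5-channel EEG matrix for a given C3 SMR envelope
synth_eeg_matrix <- function(n, fs, profile, envelope) {
  tt <- (seq_len(n) - 1L) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  smr <- sqrt(2) * envelope *
    sin(2 * pi * profile$smr_center_freq * tt + phase)
  common <- pink_noise(n, fs, 0.5 * profile$noise_level)
  m <- matrix(0, nrow = length(EEG_CHANNELS), ncol = n,
              dimnames = list(EEG_CHANNELS, NULL))
  for (ch in EEG_CHANNELS)
    m[ch, ] <- pink_noise(n, fs, profile$noise_level) + common
  m["C3", ] <- m["C3", ] + smr
  m
}

#' Generate a motor-imagery calibration EEG recording
#'
#' Emulates the SMR-ERD calibration protocol: `n_trials` externally paced
#' imagery trials of `trial_len` seconds, each followed by a rest
#' inter-trial interval (ITI) of `iti` seconds.  The C3 channel carries the
#' participant's SMR at full amplitude during ITIs and attenuated by
#' `erd_depth` during imagery.  Annotations mark every imagery onset and
#' offset (`imagery_start` / `imagery_end`, with the trial index).
#'
#' @param profile a [participant_profile()].
#' @param n_trials number of imagery trials (study protocol: 42).
#' @param trial_len imagery trial length in seconds (study protocol: 5).
#' @param iti inter-trial rest interval in seconds (study protocol: 4).
#' @param seed optional seed override; defaults to `profile$rng_seed`.
#' @return A [signal_recording()] of duration `n_trials * (trial_len + iti)`
#'   seconds at 1 kHz.
#' @export
generate_calibration_eeg <- function(profile, n_trials = 42L, trial_len = 5,
                                     iti = 4, seed = profile$rng_seed) {
  stopifnot(inherits(profile, "participant_profile"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (trial_len <= 0 || iti <= 0)
    stop("trial_len and iti must be positive")
  fs <- 1000
  dur <- n_trials * (trial_len + iti)
  n <- round(dur * fs)
  onsets <- (seq_len(n_trials) - 1L) * (trial_len + iti)
  epochs <- data.frame(onset = onsets, offset = onsets + trial_len)
  with_seed(seed, {
    env <- erd_envelope(n, fs, profile$smr_amplitude,
                        profile$smr_amplitude * (1 - profile$erd_depth),
                        epochs)
    m <- synth_eeg_matrix(n, fs, profile, env)
    ann <- data.frame(
      time = c(epochs$onset, epochs$offset),
      label = rep(c("imagery_start", "imagery_end"), each = n_trials),
      trial_index = rep(seq_len(n_trials), 2L))
    signal_recording(m, fs, EEG_CHANNELS, ann)
  })
}

# one saccade pulse sampled on a relative time axis (seconds from onset)
hov_pulse_shape <- function(trel) {
  up <- 1 / (1 + exp(-(trel - HOV_RISE / 2) / (HOV_RISE / 8)))
  t_off <- HOV_RISE + HOV_HOLD
  down <- 1 / (1 + exp(-(trel - t_off - HOV_RISE / 2) / (HOV_RISE / 8)))
  up - down
}

# add signed pulses to a bipolar pair; returns list(EOGL, EOGR) increments
add_hov_pulses <- function(n, fs, onsets, signs, amplitude) {
  tt <- (seq_len(n) - 1L) / fs
  bip <- numeric(n)
  for (k in seq_along(onsets)) {
    idx <- which(tt >= onsets[k] & tt < onsets[k] + HOV_RISE * 2 + HOV_HOLD + 0.5)
    bip[idx] <- bip[idx] +
      signs[k] * amplitude * hov_pulse_shape(tt[idx] - onsets[k])
  }
  bip
}

#' Generate a paced HOV calibration EOG recording
#'
#' Emulates the oculoversion calibration protocol: externally paced maximal
#' horizontal eye movements, one smoothed step of `+/- hov_amplitude`
#' (bipolar EOGR - EOGL) per paced movement.  Movements are paced every
#' `pace` seconds after a `lead_in` baseline.  Annotations carry the
#' ground-truth direction (`hov_left` / `hov_right`) and onset time.
#'
#' @param profile a [participant_profile()].
#' @param n_movements number of paced movements (study protocol: 10).
#' @param direction_sequence character vector of `"left"`/`"right"` of
#'   length `n_movements`.
#' @param pace seconds between paced movements.
#' @param lead_in baseline seconds before the first movement.
#' @param seed optional seed override; defaults to `profile$rng_seed + 1`.
#' @return A [signal_recording()] with channels `EOGL`, `EOGR` at 1 kHz.
#' @export
generate_hov_calibration_eog <- function(profile, n_movements = 10L,
                                         direction_sequence =
                                           rep(c("right", "left"),
                                               length.out = n_movements),
                                         pace = 4, lead_in = 2,
                                         seed = profile$rng_seed + 1L) {
  stopifnot(inherits(profile, "participant_profile"))
  if (n_movements < 1 || length(direction_sequence) == 0L)
    stop("direction_sequence must be non-empty")
  if (length(direction_sequence) != n_movements)
    stop("n_movements must equal length(direction_sequence)")
  if (!all(direction_sequence %in% c("left", "right")))
    stop("direction_sequence entries must be 'left' or 'right'")
  fs <- 1000
  onsets <- lead_in + (seq_len(n_movements) - 1L) * pace
  dur <- lead_in + n_movements * pace
  n <- round(dur * fs)
  signs <- ifelse(direction_sequence == "right", 1, -1)
  with_seed(seed, {
    bip <- add_hov_pulses(n, fs, onsets, signs, profile$hov_amplitude)
    m <- rbind(EOGL = -bip / 2 + pink_noise(n, fs, profile$noise_level),
               EOGR = bip / 2 + pink_noise(n, fs, profile$noise_level))
    ann <- data.frame(time = onsets,
                      label = paste0("hov_", direction_sequence),
                      trial_index = seq_len(n_movements))
    signal_recording(m, fs, EOG_CHANNELS, ann)
  })
}

# nominal planner constants: conservative decoder delays so that the FSM is
# always awaiting input before the planned cue of the next sub-task
PLAN_SLACK <- 0.5      # s, planned cue after planned state readiness
PLAN_DELTA_HOV <- 0.2  # s, assumed HOV detection delay
PLAN_DELTA_ERD <- 1.0  # s, assumed ERD detection delay margin
PLAN_REP_ITI <- 2.0    # s, pause between repetitions
ERD_EPOCH_EXTRA <- 2.5 # s, sustained ERD beyond the mechanism time

# plan one sub-task initialization relative to nominal readiness `ready`.
# Synchronous mode: the display cue is scheduled PLAN_SLACK after readiness;
# a pre-activation pushes the cue `lead` seconds further so the intent
# genuinely precedes it.  Asynchronous mode: the metric reference is the
# state-entry time, so a pre-activation instead starts the intent up to
# `safe_back` seconds BEFORE readiness (during the preceding automatic
# motion, where the decoder runs but the supervisor does not yet act);
# `safe_back = 0` (saccade commands, which the supervisor would discard)
# degenerates to an immediate post-readiness action.
plan_subtask <- function(ready, lat_mean, lat_sd, pre_prob, lead_mean,
                         mode, safe_back = 0) {
  pre <- stats::runif(1) < pre_prob
  if (!pre) {
    cue <- ready + PLAN_SLACK
    return(list(cue = cue, onset = cue + rlatency(1, lat_mean, lat_sd)))
  }
  lead <- stats::rexp(1, 1 / lead_mean)
  if (mode == "synchronous") {
    onset <- ready + PLAN_SLACK
    list(cue = onset + lead, onset = onset)
  } else {
    onset <- if (safe_back > 0) ready - min(lead, safe_back) else ready + 0.05
    list(cue = ready + PLAN_SLACK, onset = onset)
  }
}

#' Generate a full task session (EEG + EOG + ground-truth annotations)
#'
#' Realizes the trial structure of the drinking/pouring experiment for one
#' condition: for each repetition, a gaze selection (sub-task 1), two HOV
#' intents (reach, sub-task 2; place back, sub-task 4) and two sustained ERD
#' intents (grasp, sub-task 3; release, sub-task 5) are emitted.  Intent
#' onsets are drawn from the condition's log-normal latency distribution;
#' with probability `pre_activation_prob` the intent precedes its cue by an
#' exponential lead.  Cue times are planned forward with conservative
#' nominal decoder delays so the shared-control machine is awaiting input
#' when each cue arrives.
#'
#' @param profile a [participant_profile()] with latency parameters for the
#'   plan's condition.
#' @param plan a [session_plan()].
#' @param device a [device_model()]; defaults to the plan's device.
#' @param erd_gain factor by which the amplitude-attenuation depth of
#'   task-session ERD epochs exceeds the profile's calibration
#'   `erd_depth` (capped at 0.95).  The calibrated detection threshold is
#'   the average elicited ERD, i.e. the middle of the calibration
#'   distribution; operable online control therefore presumes the user
#'   elicits deeper desynchronization during feedback-guided operation
#'   than the calibration average.  The default 1.5 places task epochs at
#'   1.5x the calibrated depth.
#' @return An object of class `task_session`: list with elements `eeg`,
#'   `eog` (both [signal_recording()]), `annotations` (the session event
#'   table: planned cues, ground-truth intents), `plan`, `device`.
#' @export
generate_task_session <- function(profile, plan,
                                  device = device_model(plan$device),
                                  erd_gain = 1.5) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(plan, "session_plan"))
  key <- condition_key(plan$device, plan$mode)
  lat_mean <- profile_param(profile, "latency_mean", key)
  lat_sd <- profile_param(profile, "latency_sd", key)
  pre_prob <- profile_param(profile, "pre_activation_prob", key)
  lead_mean <- profile$pre_activation_lead_mean
  fs <- 1000
  object_id <- if (plan$task == "drinking") "glass" else "bottle"

  with_seed(plan$seed, {
    rows <- list()
    add <- function(time, label, rep) {
      rows[[length(rows) + 1L]] <<-
        data.frame(time = time, label = label, trial_index = rep)
    }
    t0 <- 1.0
    draw <- function(ready, safe_back = 0)
      plan_subtask(ready, lat_mean, lat_sd, pre_prob, lead_mean,
                   plan$mode, safe_back)
    for (r in seq_len(plan$n_repetitions)) {
      # S1: gaze selection (awaited since the previous home return)
      p1 <- draw(t0, safe_back = min(PLAN_REP_ITI, t0) - 0.5)
      add(p1$cue, "cue:s1", r)
      add(p1$onset, paste0("intent:s1:gaze:", object_id), r)
      # S2: reach via right HOV
      p2 <- draw(p1$onset + device$select_confirm)
      add(p2$cue, "cue:s2", r)
      add(p2$onset, "intent:s2:hov_right", r)
      # S3: grasp via sustained ERD (may be anticipated during the reach,
      # by at most the sustained-epoch slack), then automatic transport
      erd_back <- min(device$reach_duration, ERD_EPOCH_EXTRA) - 0.5
      r3 <- p2$onset + PLAN_DELTA_HOV + device$reach_duration
      p3 <- draw(r3, safe_back = erd_back)
      add(p3$cue, "cue:s3", r)
      add(p3$onset, "intent:s3:erd_on", r)
      add(p3$onset + device$erd_duration + ERD_EPOCH_EXTRA,
          "intent:s3:erd_off", r)
      # S4: place back via right HOV; an anticipated grasp epoch still
      # completes no earlier than state entry + mechanism time
      p4 <- draw(max(p3$onset, r3) + PLAN_DELTA_ERD + device$erd_duration +
                   device$transport_duration)
      add(p4$cue, "cue:s4", r)
      add(p4$onset, "intent:s4:hov_right", r)
      # S5: release via sustained ERD (may be anticipated during the
      # placing motion), then automatic home return
      r5 <- p4$onset + PLAN_DELTA_HOV + device$return_duration
      p5 <- draw(r5, safe_back = min(device$return_duration,
                                     ERD_EPOCH_EXTRA) - 0.5)
      add(p5$cue, "cue:s5", r)
      add(p5$onset, "intent:s5:erd_on", r)
      add(p5$onset + device$erd_duration + ERD_EPOCH_EXTRA,
          "intent:s5:erd_off", r)
      t0 <- max(p5$onset, r5) + PLAN_DELTA_ERD + device$erd_duration +
        device$return_duration + PLAN_REP_ITI
    }
    ann <- do.call(rbind, rows)
    dur <- t0 + 1.0
    n <- round(dur * fs)

    erd_on <- ann$time[grepl(":erd_on$", ann$label)]
    erd_off <- ann$time[grepl(":erd_off$", ann$label)]
    epochs <- data.frame(onset = sort(erd_on), offset = sort(erd_off))
    depth <- min(0.95, profile$erd_depth * erd_gain)
    env <- erd_envelope(n, fs, profile$smr_amplitude,
                        profile$smr_amplitude * (1 - depth),
                        epochs)
    eeg <- signal_recording(synth_eeg_matrix(n, fs, profile, env), fs,
                            EEG_CHANNELS, ann)

    hov_t <- ann$time[grepl(":hov_right$", ann$label)]
    bip <- add_hov_pulses(n, fs, hov_t, rep(1, length(hov_t)),
                          profile$hov_amplitude)
    eog <- signal_recording(
      rbind(EOGL = -bip / 2 + pink_noise(n, fs, profile$noise_level),
            EOGR = bip / 2 + pink_noise(n, fs, profile$noise_level)),
      fs, EOG_CHANNELS, ann)

    structure(list(eeg = eeg, eog = eog, annotations = ann,
                   plan = plan, device = device,
                   profile_id = profile$id),
              class = "task_session")
  })
}

#' @export
print.task_session <- function(x, ...) {
  cat(sprintf("<task_session> %s/%s/%s: %d repetition(s), %.1f s\n",
              x$plan$device, x$plan$mode, x$plan$task,
              x$plan$n_repetitions, duration(x$eeg)))
  invisible(x)
}
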