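#' Virtual participant profile
#'
#' Generative parameters of one virtual BCI user: the subject-specific
#' sensorimotor rhythm (SMR) and how deeply motor imagery attenuates it
#' (event-related desynchronization, ERD), electrooculogram saccade
#' amplitude, background noise, and condition-dependent reaction behaviour.
#'
#' Latency and pre-activation parameters may be single numbers (applied to
#' every condition) or vectors named by condition key
#' (`"exoskeleton.synchronous"`, `"exoskeleton.asynchronous"`,
#' `"manipulator.synchronous"`, `"manipulator.asynchronous"`).
#' Reaction latencies are drawn from a log-normal distribution
#' moment-matched to `latency_mean`/`latency_sd`; pre-activation leads are
#' exponential with mean `pre_activation_lead_mean`.
#'
#' @param id text label for the participant.
#' @param smr_center_freq SMR center frequency in Hz, within [8, 13].
#' @param smr_amplitude resting SMR amplitude at C3, microvolt RMS.
#' @param erd_depth fraction in [0, 1] by which the SMR amplitude is
#'   attenuated during motor imagery.
#' @param noise_level broadband (1/f-shaped) background noise, microvolt RMS.
#' @param hov_amplitude peak bipolar deflection of a maximal horizontal
#'   oculoversion, microvolts.
#' @param latency_mean,latency_sd mean and sd (seconds) of the cue-to-intent
#'   reaction latency, per condition.
#' @param pre_activation_prob probability that intent onset precedes the cue.
#' @param pre_activation_lead_mean mean lead (seconds, positive) of
#'   pre-cue intent onsets.
#' @param rng_seed integer seed fixing all randomness derived from this
#'   profile.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(id = "P01",
                                smr_center_freq = 11,
                                smr_amplitude = 5,
                                erd_depth = 0.5,
                                noise_level = 2,
                                hov_amplitude = 250,
                                latency_mean = c(exoskeleton.synchronous = 1.3,
                                                 exoskeleton.asynchronous = 1.1,
                                                 manipulator.synchronous = 1.9,
                                                 manipulator.asynchronous = 1.5),
                                latency_sd = 0.5,
                                pre_activation_prob = 0.3,
                                pre_activation_lead_mean = 1.5,
                                rng_seed = 1L) {
  stopifnot(smr_center_freq >= 8, smr_center_freq <= 13,
            erd_depth >= 0, erd_depth <= 1,
            smr_amplitude > 0, hov_amplitude > 0, noise_level >= 0,
            all(latency_sd >= 0),
            all(pre_activation_prob >= 0), all(pre_activation_prob <= 1),
            pre_activation_lead_mean > 0)
  structure(list(id = as.character(id),
                 smr_center_freq = smr_center_freq,
                 smr_amplitude = smr_amplitude,
                 erd_depth = erd_depth,
                 noise_level = noise_level,
                 hov_amplitude = hov_amplitude,
                 latency_mean = latency_mean,
                 latency_sd = latency_sd,
                 pre_activation_prob = pre_activation_prob,
                 pre_activation_lead_mean = pre_activation_lead_mean,
                 rng_seed = as.integer(rng_seed)),
            class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("<participant_profile> %s: SMR %.1f Hz @ %.1f uV RMS, ERD depth %.2f, noise %.1f uV\n",
              x$id, x$smr_center_freq, x$smr_amplitude, x$erd_depth,
              x$noise_level))
  invisible(x)
}

#' Condition key for a device/mode pair
#' @param device `"exoskeleton"` or `"manipulator"`.
#' @param mode `"synchronous"` or `"asynchronous"`.
#' @return A string such as `"exoskeleton.synchronous"`.
#' @export
condition_key <- function(device, mode) {
  device <- match.arg(device, c("exoskeleton", "manipulator"))
  mode <- match.arg(mode, c("synchronous", "asynchronous"))
  paste(device, mode, sep = ".")
}

# internal: look up a possibly condition-keyed profile parameter
profile_param <- function(profile, field, key) {
  v <- profile[[field]]
  if (length(v) == 1L && is.null(names(v))) return(unname(v))
  if (!key %in% names(v))
    stop("profile '", profile$id, "': no value of ", field,
         " for condition '", key, "'")
  unname(v[[key]])
}

# internal: log-normal draw moment-matched to (mean, sd); sd 0 degenerates
rlatency <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Session plan for one experimental condition
#'
#' @param task `"drinking"` or `"pouring"`.
#' @param mode `"synchronous"` (cued) or `"asynchronous"` (self-paced).
#' @param device `"exoskeleton"` or `"manipulator"`.
#' @param n_repetitions number of task repetitions (10 in the study design).
#' @param seed integer seed for the session's randomness.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(task = c("drinking", "pouring"),
                         mode = c("synchronous", "asynchronous"),
                         device = c("exoskeleton", "manipulator"),
                         n_repetitions = 10L, seed = 1L) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  device <- match.arg(device)
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  structure(list(task = task, mode = mode, device = device,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %s task, %s mode, %s, %d repetition(s)\n",
              x$task, x$mode, x$device, x$n_repetitions))
  invisible(x)
}
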