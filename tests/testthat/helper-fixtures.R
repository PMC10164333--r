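# Shared fixtures and independent oracles for the test suite.

# memoised expensive fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

quiet_profile <- function(...) {
  defaults <- list(id = "test", smr_center_freq = 11, smr_amplitude = 5,
                   erd_depth = 0.5, noise_level = 2, hov_amplitude = 250,
                   latency_mean = 1.2, latency_sd = 0.3,
                   pre_activation_prob = 0, rng_seed = 101L)
  do.call(participant_profile, utils::modifyList(defaults, list(...)))
}

# calibrated decoders for a default test participant (reused widely)
test_erd_cal <- function() fixture("erd_cal", function() {
  prof <- quiet_profile()
  suppressWarnings(erd_calibrate(
    generate_calibration_eeg(prof, n_trials = 14L),
    generate_calibration_eeg(prof, n_trials = 14L, seed = 202L)))
})

test_hov_cal <- function() fixture("hov_cal", function() {
  hov_calibrate(generate_hov_calibration_eog(quiet_profile()))
})

# a decoded synchronous exoskeleton session and its task log
test_session <- function() fixture("session", function() {
  prof <- quiet_profile()
  plan <- session_plan("drinking", "synchronous", "exoskeleton", 3L,
                       seed = 303L)
  sess <- generate_task_session(prof, plan)
  log <- run_task_session(sess, test_erd_cal(), test_hov_cal())
  list(sess = sess, log = log,
       metrics = trial_metrics(log, sess$device))
})

# FFT periodogram band power: independent oracle for the Burg estimator
pgram_band_power <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  psd <- Mod(stats::fft(x))^2 / (n * fs)   # two-sided
  f <- (seq_len(n) - 1L) * fs / n
  sel <- f >= band[1] & f <= band[2]
  2 * sum(psd[sel]) * fs / n
}

# single-channel recording with imagery annotations, for decoder unit tests
annotated_single_channel <- function(x, fs, epochs) {
  ann <- data.frame(
    time = c(epochs$onset, epochs$offset),
    label = rep(c("imagery_start", "imagery_end"), each = nrow(epochs)),
    trial_index = rep(seq_len(nrow(epochs)), 2L))
  signal_recording(matrix(x, nrow = 1L), fs, "C3-lap", ann)
}

# brute-force Wilcoxon-Pratt oracle: rank |d| with zeros, enumerate all
# sign assignments of the non-zero ranks (independent of the implementation)
wilcoxon_pratt_oracle <- function(d) {
  r <- rank(abs(d))
  rnz <- r[d != 0]
  v_obs <- sum(r[d > 0])
  s <- sum(rnz)
  m <- length(rnz)
  ws <- vapply(0:(2^m - 1), function(bits) {
    sum(rnz[as.logical(bitwAnd(bits, 2^(seq_len(m) - 1L)))])
  }, numeric(1))
  list(statistic = v_obs,
       p_value = mean(abs(ws - s / 2) >= abs(v_obs - s / 2) - 1e-9))
}
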