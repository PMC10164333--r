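test_that("calibration EEG has the protocol duration and annotations", {
  prof <- quiet_profile()
  rec <- generate_calibration_eeg(prof, n_trials = 42L, trial_len = 5,
                                  iti = 4)
  expect_equal(duration(rec), 42 * 9)           # 42 x (5 + 4) s
  expect_equal(rec$fs, 1000)
  expect_setequal(rec$channel_labels, c("F3", "T3", "C3", "Cz", "P3"))
  ann <- rec$annotations
  expect_equal(sum(ann$label == "imagery_start"), 42L)
  expect_equal(sum(ann$label == "imagery_end"), 42L)
  expect_error(generate_calibration_eeg(prof, trial_len = 0),
               "positive")
  expect_error(generate_calibration_eeg(prof, n_trials = 0), ">= 1")
})

test_that("imagery attenuates C3 band power by the squared ERD depth", {
  fs <- 1000
  band <- c(9.5, 12.5)
  seg_power <- function(rec, t0, t1)
    pgram_band_power(channel(rec, "C3")[(t0 * fs):(t1 * fs)], fs, band)
  # erd_depth 0.5, noiseless: imagery/rest power ratio = (1 - 0.5)^2
  prof <- quiet_profile(noise_level = 1e-3, erd_depth = 0.5)
  rec <- generate_calibration_eeg(prof, n_trials = 4L)
  # interior of trial 2 (imagery) vs its ITI (rest), away from ramps
  p_im <- seg_power(rec, 9.5, 13.5)
  p_rest <- seg_power(rec, 14.5, 17.5)
  expect_equal(p_im / p_rest, 0.25, tolerance = 0.05)
  # erd_depth 0: no contrast
  rec0 <- generate_calibration_eeg(quiet_profile(noise_level = 1e-3,
                                                 erd_depth = 0),
                                   n_trials = 4L)
  expect_equal(seg_power(rec0, 9.5, 13.5) / seg_power(rec0, 14.5, 17.5),
               1, tolerance = 0.05)
})

test_that("rest-segment spectral peak sits at the profile's SMR frequency", {
  for (f0 in c(9, 12)) {
    prof <- quiet_profile(smr_center_freq = f0,
                          noise_level = quiet_profile()$smr_amplitude / 2)
    rec <- generate_calibration_eeg(prof, n_trials = 8L)  # 28 s of rest
    fs <- rec$fs
    # concatenate all ITIs (5..9 s of each 9 s cycle, inside the ramps)
    idx <- unlist(lapply(seq_len(8) - 1L, function(k)
      seq((k * 9 + 5.4) * fs, (k * 9 + 8.9) * fs)))
    x <- channel(rec, "C3")[idx]
    spec <- Mod(stats::fft(x - mean(x)))^2
    f <- (seq_along(x) - 1L) * fs / length(x)
    inband <- f >= 7 & f <= 14
    fpeak <- f[inband][which.max(spec[inband])]
    expect_lt(abs(fpeak - f0), 0.5)
  }
})

test_that("HOV calibration recording carries the paced deflections", {
  prof <- quiet_profile(noise_level = 0)
  rec <- generate_hov_calibration_eog(prof, 10L, rep("right", 10L))
  bip <- channel(rec, "EOGR") - channel(rec, "EOGL")
  peaks <- vapply(rec$annotations$time, function(t0)
    max(bip[(t0 * 1000):((t0 + 2) * 1000)]), numeric(1))
  expect_length(peaks, 10L)
  expect_true(all(peaks > 0))
  expect_equal(max(peaks) - min(peaks), 0, tolerance = 1e-6)
  # alternating directions alternate in sign
  rec2 <- generate_hov_calibration_eog(prof, 4L,
                                       c("left", "right", "left", "right"))
  bip2 <- channel(rec2, "EOGR") - channel(rec2, "EOGL")
  signs <- vapply(rec2$annotations$time, function(t0) {
    seg <- bip2[(t0 * 1000):((t0 + 2) * 1000)]
    sign(seg[which.max(abs(seg))])
  }, numeric(1))
  expect_equal(signs, c(-1, 1, -1, 1))
  expect_error(generate_hov_calibration_eog(prof, 0L, character(0)),
               "non-empty")
  expect_error(generate_hov_calibration_eog(prof, 3L, c("left", "up", "x")),
               "left")
})

test_that("noisy HOV deflections estimate the profile amplitude", {
  prof <- quiet_profile(noise_level = 5)
  rec <- generate_hov_calibration_eog(prof, 10L, rep("right", 10L))
  bip <- channel(rec, "EOGR") - channel(rec, "EOGL")
  # sample the sustained plateau (unbiased, unlike a max-over-window)
  plateau <- vapply(rec$annotations$time, function(t0)
    mean(bip[((t0 + 0.3) * 1000):((t0 + 0.8) * 1000)]), numeric(1))
  se <- stats::sd(plateau) / sqrt(length(plateau))
  expect_lt(abs(mean(plateau) - prof$hov_amplitude), 3 * se)
})

test_that("task-session intent timing honours the latency model", {
  # degenerate latency: all onsets exactly cue + 1.0 s
  prof <- quiet_profile(latency_mean = 1.0, latency_sd = 0,
                        pre_activation_prob = 0)
  sess <- generate_task_session(prof, session_plan(n_repetitions = 3L,
                                                   seed = 5L))
  ann <- sess$annotations
  cues <- ann[grepl("^cue:", ann$label), ]
  intents <- ann[grepl("^intent:", ann$label) &
                   !grepl("erd_off", ann$label), ]
  cues$sub <- sub("^cue:", "", cues$label)
  intents$sub <- sub("^intent:(s[1-5]).*$", "\\1", intents$label)
  m <- merge(cues, intents, by = c("trial_index", "sub"))
  expect_equal(nrow(m), 15L)  # 3 reps x 5 sub-tasks
  expect_equal(m$time.y - m$time.x, rep(1.0, 15L))
  # pre_activation_prob 1: every intent onset precedes its cue
  prof1 <- quiet_profile(pre_activation_prob = 1)
  sess1 <- generate_task_session(prof1, session_plan(n_repetitions = 3L,
                                                     seed = 6L))
  ann1 <- sess1$annotations
  cues1 <- ann1[grepl("^cue:", ann1$label), ]
  int1 <- ann1[grepl("^intent:", ann1$label) & !grepl("erd_off", ann1$label), ]
  cues1$sub <- sub("^cue:", "", cues1$label)
  int1$sub <- sub("^intent:(s[1-5]).*$", "\\1", int1$label)
  m1 <- merge(cues1, int1, by = c("trial_index", "sub"))
  expect_true(all(m1$time.y < m1$time.x))
})

test_that("each repetition carries 1 gaze + 2 HOV + 2 ERD intent epochs", {
  sess <- test_session()$sess
  ann <- sess$annotations
  for (r in unique(ann$trial_index)) {
    a <- ann[ann$trial_index == r, ]
    expect_equal(sum(grepl(":gaze:", a$label)), 1L)
    expect_equal(sum(grepl(":hov_right$", a$label)), 2L)
    expect_equal(sum(grepl(":erd_on$", a$label)), 2L)
  }
})

test_that("generation is bit-reproducible under a fixed seed", {
  prof <- quiet_profile()
  a <- generate_calibration_eeg(prof, n_trials = 2L)
  b <- generate_calibration_eeg(prof, n_trials = 2L)
  expect_identical(a$samples, b$samples)
  p <- session_plan(n_repetitions = 2L, seed = 9L)
  s1 <- generate_task_session(prof, p)
  s2 <- generate_task_session(prof, p)
  expect_identical(s1$eeg$samples, s2$eeg$samples)
  expect_identical(s1$eog$samples, s2$eog$samples)
  expect_identical(s1$annotations, s2$annotations)
  # generators do not perturb the caller's RNG stream
  set.seed(4); x1 <- rnorm(1)
  set.seed(4); invisible(generate_calibration_eeg(prof, n_trials = 1L))
  expect_identical(rnorm(1), x1)
})
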