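# A single-channel oscillation with annotated imagery epochs, built on a
# known analytic ground truth (sinusoid power A^2/2), drives most checks.
sine_calib <- function(A = 10, f0 = 11, depth = 0.5, n_trials = 4L,
                       noise = 0.05, fs = 1000, seed = 31) {
  dur <- n_trials * 9
  tt <- (0:(dur * fs - 1)) / fs
  onsets <- (seq_len(n_trials) - 1L) * 9
  epochs <- data.frame(onset = onsets, offset = onsets + 5)
  amp <- rep(A, length(tt))
  for (k in seq_len(n_trials))
    amp[tt >= epochs$onset[k] & tt < epochs$offset[k]] <- A * (1 - depth)
  set.seed(seed)
  x <- amp * sin(2 * pi * f0 * tt) + rnorm(length(tt), 0, noise)
  annotated_single_channel(x, fs, epochs)
}

test_that("reference value recovers the analytic power of a sinusoid", {
  A <- 10
  rec <- sine_calib(A = A)
  cal <- hybridbci:::new_erd_calibration(center_freq = 11)
  rv <- compute_rv(rec, cal)
  expect_equal(rv, A^2 / 2, tolerance = 0.05)      # A^2/2 = 50 uV^2
  # doubling the amplitude quadruples the RV
  rv2 <- compute_rv(sine_calib(A = 2 * A), cal)
  expect_equal(rv2 / rv, 4, tolerance = 0.05)
  # deterministic on the same recording
  expect_identical(rv, compute_rv(rec, cal))
  expect_error(compute_rv(signal_recording(matrix(0, 1, 1000), 1000, "C3-lap"),
                          cal), "imagery")
})

test_that("center-frequency selection tracks the generated SMR", {
  sels <- vapply(c(9, 12), function(f0) {
    prof <- quiet_profile(smr_center_freq = f0)
    rec <- generate_calibration_eeg(prof, n_trials = 10L)
    as.numeric(select_center_freq(rec))
  }, numeric(1))
  expect_lt(abs(sels[1] - 9), 0.501)
  expect_lt(abs(sels[2] - 12), 0.501)
  expect_lt(sels[1], sels[2])   # ordering follows ground truth
  # no ERD contrast: selection is flagged degenerate
  rec0 <- generate_calibration_eeg(quiet_profile(erd_depth = 0),
                                   n_trials = 8L)
  expect_warning(sel0 <- select_center_freq(rec0), "degenerate")
  expect_true(isTRUE(attr(sel0, "degenerate")))
})

test_that("ERD percent follows the power method formula", {
  # steady tone whose band power equals the reference: ERD ~ 0%
  rec <- sine_calib(depth = 0)
  cal <- hybridbci:::new_erd_calibration(center_freq = 11, rv = 50)
  tc <- erd_timecourse(rec, cal, step = 0.5)
  expect_equal(median(tc$erd_percent), 0, tolerance = 2)
  # halved band power: -50%; doubled: +100% (synchronization sign)
  cal_half <- hybridbci:::new_erd_calibration(center_freq = 11, rv = 100)
  expect_equal(median(erd_timecourse(rec, cal_half, step = 0.5)$erd_percent),
               -50, tolerance = 1)
  cal_dbl <- hybridbci:::new_erd_calibration(center_freq = 11, rv = 25)
  expect_equal(median(erd_timecourse(rec, cal_dbl, step = 0.5)$erd_percent),
               100, tolerance = 2)
  expect_error(erd_timecourse(rec, hybridbci:::new_erd_calibration(11)),
               "rv")
})

test_that("detection threshold is the mean of per-trial mean ERD", {
  tc <- structure(
    data.frame(times = seq(0.5, 30, by = 0.5),
               erd_percent = 0, active = FALSE),
    class = c("erd_timecourse", "data.frame"))
  epochs <- data.frame(onset = c(0, 10, 20), offset = c(5, 15, 25))
  tc$erd_percent[tc$times <= 5] <- -30
  tc$erd_percent[tc$times >= 10 & tc$times <= 15] <- -20
  tc$erd_percent[tc$times >= 20 & tc$times <= 25] <- -40
  expect_equal(erd_threshold(tc, epochs), -30)   # mean of {-30,-20,-40}
  expect_error(erd_threshold(tc, epochs[0, ]), "trials")
})

test_that("calibrated threshold matches the analytic amplitude model", {
  # amplitude halved => band power quartered => mean elicited ERD ~ -75%
  prof <- quiet_profile(erd_depth = 0.5, noise_level = 0.5)
  cal <- erd_calibrate(generate_calibration_eeg(prof, n_trials = 14L),
                       generate_calibration_eeg(prof, n_trials = 14L,
                                                seed = 77L))
  expect_equal(cal$threshold, -75, tolerance = 0.07)
  expect_false(isTRUE(cal$degenerate))
  # no ERD: calibration flagged non-informative
  prof0 <- quiet_profile(erd_depth = 0)
  expect_warning(
    cal0 <- erd_calibrate(generate_calibration_eeg(prof0, n_trials = 8L),
                          center_freq = 11),
    "non-informative")
  expect_true(cal0$degenerate)
  expect_equal(cal0$threshold, 0, tolerance = 6)
})

test_that("online detection opens dwell-gated activations at ERD epochs", {
  cal <- test_erd_cal()
  fs <- 1000
  dur <- 20
  tt <- (0:(dur * fs - 1)) / fs
  A <- sqrt(2 * cal$rv)                 # rest amplitude matching the RV
  amp <- rep(A, length(tt))
  amp[tt >= 8 & tt < 11] <- A * 0.2     # one deep 3 s ERD epoch
  set.seed(41)
  x <- amp * sin(2 * pi * cal$center_freq * tt) + rnorm(length(tt), 0, 0.5)
  acts <- detect_erd_online(x, cal)
  expect_equal(nrow(acts), 1L)
  expect_lt(abs(acts$onset - 8), 1.0)
  expect_lt(abs(acts$offset - 11), 1.0)
  # dwell longer than the epoch: no activation
  expect_equal(nrow(detect_erd_online(x, cal, dwell = 5)), 0L)
  # constant rest-level signal: no activations
  set.seed(42)
  xr <- A * sin(2 * pi * cal$center_freq * tt) + rnorm(length(tt), 0, 0.5)
  expect_equal(nrow(detect_erd_online(xr, cal)), 0L)
})

test_that("active flag and threshold sign convention agree everywhere", {
  cal <- test_erd_cal()
  rec <- prepped <- generate_calibration_eeg(quiet_profile(), n_trials = 2L)
  tc <- predict(cal, rec, type = "timecourse")
  expect_identical(tc$active, tc$erd_percent <= cal$threshold)
  expect_lt(cal$threshold, 0)
})

test_that("calibration state survives a JSON round trip", {
  cal <- test_erd_cal()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_calibration_json(cal, path)
  back <- read_calibration_json(path)
  expect_s3_class(back, "erd_calibration")
  expect_equal(back$rv, cal$rv)
  expect_equal(back$threshold, cal$threshold)
  expect_equal(back$center_freq, cal$center_freq)
})
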