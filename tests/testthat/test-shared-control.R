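exo <- device_model("exoskeleton")
jaco <- device_model("manipulator")

# drive the machine over a vector of tick inputs, collecting the log
drive <- function(fsm, inputs, device = exo, t0 = 0,
                  mode = "synchronous") {
  recs <- list()
  t <- t0
  for (inp in inputs) {
    st <- fsm_step(fsm, t, inp, device, mode)
    fsm <- st$fsm
    if (!is.null(st$records)) recs[[length(recs) + 1L]] <- st$records
    t <- t + 0.01
  }
  list(fsm = fsm, log = if (length(recs)) do.call(rbind, recs) else NULL)
}

idle <- list(erd_active = FALSE)
n_idle <- function(n) rep(list(idle), n)

to_state <- function(state, phase, rep = 1L) {
  fsm <- fsm_init()
  fsm$state <- state
  fsm$phase <- phase
  fsm$rep <- rep
  fsm
}

test_that("the transition table matches the written control policy", {
  # S1 await_gaze: gaze selects; HOV is ignored
  st <- fsm_step(fsm_init(), 0, list(gaze_id = "glass"), exo)
  expect_equal(st$fsm$phase, "confirm")
  expect_equal(st$log <- st$records$event[1], "gaze_select")
  st2 <- fsm_step(fsm_init(), 0, list(hov = "right"), exo)
  expect_equal(st2$fsm$phase, "await_gaze")
  expect_match(st2$records$detail[1], "ignored")
  # confirm: left HOV vetoes back to await_gaze
  stv <- fsm_step(st$fsm, 0.5, list(hov = "left"), exo)
  expect_equal(stv$fsm$phase, "await_gaze")
  expect_equal(stv$records$event[1], "veto")
  expect_null(stv$fsm$selected)
  # confirm: timeout enters S2
  stc <- drive(st$fsm, n_idle(110), t0 = 0.01)
  expect_equal(stc$fsm$state, "S2")
  expect_equal(stc$fsm$phase, "await_hov")
  # S2: right HOV starts the automatic reach; left HOV is ignored
  s2 <- to_state("S2", "await_hov")
  expect_match(fsm_step(s2, 0, list(hov = "left"), exo)$records$detail[1],
               "ignored")
  go <- fsm_step(s2, 0, list(hov = "right"), exo)
  expect_equal(go$fsm$phase, "auto_reach")
  expect_setequal(go$records$event, c("hov", "motion_start"))
  # S3: an HOV event cannot trigger anything (concurrency prohibition)
  s3 <- to_state("S3", "hand")
  h <- fsm_step(s3, 0, list(hov = "right", erd_active = FALSE), exo)
  expect_equal(h$fsm$state, "S3")
  expect_equal(h$fsm$phase, "hand")
  expect_match(h$records$detail[1], "ignored")
  # automatic motion ignores all user input until completion
  auto <- to_state("S2", "auto_reach")
  auto$auto_end <- 5; auto$auto_detail <- "reach"
  a <- fsm_step(auto, 1, list(hov = "right", gaze_id = "x",
                              erd_active = TRUE), exo)
  expect_equal(a$fsm$phase, "auto_reach")
  # reach completion enters S3
  done <- fsm_step(auto, 5, idle, exo)
  expect_equal(done$fsm$state, "S3")
  expect_equal(done$records$event, c("motion_complete", "state_enter"))
  # malformed input rejected
  expect_error(fsm_step(fsm_init(), 0, list(hov = "up"), exo), "malformed")
  expect_error(fsm_step(fsm_init(), 0, "x", exo), "malformed")
})

test_that("continuous ERD closes the hand in exactly the mechanism time", {
  for (dev in list(exo, jaco)) {
    n <- dev$erd_duration / 0.01
    run <- drive(to_state("S3", "hand"),
                 rep(list(list(erd_active = TRUE)), n + 10), device = dev)
    comp <- run$log[run$log$event == "motion_complete", ]
    expect_equal(nrow(comp), 1L)
    expect_match(comp$detail, sprintf("grasp:commanded=%.2f",
                                      dev$erd_duration))
    start <- run$log$time[run$log$event == "motion_start" &
                            run$log$detail == "grasp"]
    expect_equal(comp$time - start, dev$erd_duration, tolerance = 0.0101)
    expect_equal(run$fsm$phase, "auto_transport")
  }
})

test_that("pause/resume accumulates commanded time across interruptions", {
  inputs <- c(rep(list(list(erd_active = TRUE)), 100),   # 1.0 s commanded
              n_idle(50),                                 # 0.5 s paused
              rep(list(list(erd_active = TRUE)), 60))     # 0.5 s to finish
  run <- drive(to_state("S3", "hand"), inputs)
  lg <- run$log
  expect_equal(sum(lg$event == "motion_pause"), 1L)
  comp <- lg[lg$event == "motion_complete", ]
  expect_match(comp$detail, "grasp:commanded=1.50")
  # elapsed = 1.0 + 0.5 + 0.5 = 2.0 s from the FIRST motion_start
  # (the post-pause resume logs a second one)
  start <- lg$time[lg$event == "motion_start" & lg$detail == "grasp"]
  expect_length(start, 2L)
  expect_equal(comp$time - start[1], 2.0, tolerance = 0.0101)
})

test_that("ERD shorter than the mechanism time leaves the hand unfinished", {
  run <- drive(to_state("S3", "hand"),
               c(rep(list(list(erd_active = TRUE)), 100), n_idle(100)))
  expect_equal(sum(run$log$event == "motion_complete"), 0L)
  expect_equal(run$fsm$state, "S3")
  expect_equal(run$fsm$hand_progress, 1.0, tolerance = 1e-9)
})

test_that("S5 release completes into the automatic home return and S1", {
  run <- drive(to_state("S5", "hand"),
               rep(list(list(erd_active = TRUE)), 160))
  expect_equal(run$fsm$phase, "auto_home")
  run2 <- drive(run$fsm, n_idle(520), t0 = 1.60)
  expect_equal(run2$fsm$state, "S1")
  expect_equal(run2$fsm$rep, 2L)
})

test_that("a decoded session logs five states in order and is replayable", {
  ts <- test_session()
  lg <- ts$log
  for (r in 1:3) {
    ent <- lg[lg$event == "state_enter" & lg$rep == r, ]
    expect_equal(ent$state[1:5], c("S1", "S2", "S3", "S4", "S5"))
  }
  expect_true(all(diff(lg$time) >= 0))
  # bit-identical replay on identical inputs
  log2 <- run_task_session(ts$sess, test_erd_cal(), test_hov_cal())
  expect_identical(as.data.frame(lg), as.data.frame(log2))
})

test_that("a session with no detectable ERD stalls in S3", {
  ts <- test_session()
  dead_cal <- test_erd_cal()
  dead_cal$threshold <- -99.99   # effectively never crossed
  lg <- run_task_session(ts$sess, dead_cal, test_hov_cal())
  expect_equal(sum(lg$event == "motion_complete" &
                     grepl("^grasp", lg$detail)), 0L)
  tm <- trial_metrics(lg, ts$sess$device)
  expect_false(any(tm$success[tm$subtask == "s3"]))
})
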