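#' Study configuration
#'
#' Describes a whole simulated experiment: the virtual participants, the
#' conditions (devices x modes x tasks x repetitions), the calibration
#' protocol sizes and the decoder parameters.  The `master_seed` fixes all
#' downstream randomness, so re-running the same configuration reproduces
#' every output bit-identically.
#'
#' @param n_participants number of virtual participants (study design: 10).
#' @param devices,modes,tasks condition factors to cross.
#' @param n_repetitions repetitions per task session (study design: 10).
#' @param calib_trials,calib_trial_len,calib_iti SMR-ERD calibration
#'   protocol (study design: 42 trials of 5 s, 4 s ITI).
#' @param hov_movements paced maximal oculoversions for HOV calibration
#'   (study design: 10).
#' @param search_band,ar_order,window_len,step,dwell ERD decoder
#'   parameters, see [erd_calibrate()].
#' @param heterogeneity relative sd of the log-normal jitter applied to
#'   per-participant SMR frequency span, ERD depth and latencies.
#' @param master_seed integer master seed.
#' @param out_dir default output directory for [run_study()].
#' @param participants optional list of [participant_profile()]s; when
#'   supplied, `n_participants` and `heterogeneity` are ignored.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_participants = 10L,
                         devices = c("exoskeleton", "manipulator"),
                         modes = c("synchronous", "asynchronous"),
                         tasks = c("drinking", "pouring"),
                         n_repetitions = 10L,
                         calib_trials = 42L, calib_trial_len = 5,
                         calib_iti = 4, hov_movements = 10L,
                         search_band = c(8, 13), ar_order = 100L,
                         window_len = 0.5, step = 0.04, dwell = 0.2,
                         heterogeneity = 0.15, master_seed = 1L,
                         out_dir = "study_output",
                         participants = NULL) {
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  if (calib_trials < 1) stop("calib_trials must be >= 1")
  stopifnot(all(devices %in% c("exoskeleton", "manipulator")),
            all(modes %in% c("synchronous", "asynchronous")),
            all(tasks %in% c("drinking", "pouring")))
  structure(list(n_participants = as.integer(n_participants),
                 devices = devices, modes = modes, tasks = tasks,
                 n_repetitions = as.integer(n_repetitions),
                 calib_trials = as.integer(calib_trials),
                 calib_trial_len = calib_trial_len, calib_iti = calib_iti,
                 hov_movements = as.integer(hov_movements),
                 search_band = search_band, ar_order = as.integer(ar_order),
                 window_len = window_len, step = step, dwell = dwell,
                 heterogeneity = heterogeneity,
                 master_seed = as.integer(master_seed),
                 out_dir = out_dir, participants = participants),
            class = "study_config")
}

#' Write / read a study configuration as YAML
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return The path (write) or a `study_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(is.null(config$participants))  # profile lists stay in code
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(study_config, obj)
}

# deterministic 31-bit sub-seed from the master seed and a stage path
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (k in c(...)) {
    k <- if (is.character(k)) sum(as.integer(charToRaw(k))) else as.numeric(k)
    h <- (h * 48271 + k) %% 2147483647
  }
  as.integer(h)
}

# per-participant profiles with modest log-normal heterogeneity
study_profiles <- function(config) {
  if (!is.null(config$participants)) return(config$participants)
  lapply(seq_len(config$n_participants), function(i) {
    with_seed(derive_seed(config$master_seed, "profile", i), {
      jit <- function(x) x * stats::rlnorm(1, 0, config$heterogeneity)
      participant_profile(
        id = sprintf("P%02d", i),
        smr_center_freq = min(13, max(8, stats::runif(1, 9, 12))),
        erd_depth = min(0.9, max(0.2, jit(0.5))),
        latency_mean = vapply(c(exoskeleton.synchronous = 1.3,
                                exoskeleton.asynchronous = 1.1,
                                manipulator.synchronous = 1.9,
                                manipulator.asynchronous = 1.5),
                              jit, numeric(1)),
        rng_seed = derive_seed(config$master_seed, "signals", i))
    })
  })
}

#' Run the whole simulated study
#'
#' For every participant: generates the SMR-ERD and HOV calibration
#' recordings, calibrates both decoders, then simulates and decodes every
#' session (device x mode x task), runs the shared-control machine and
#' extracts the per-trial feasibility metrics.  Aggregates condition
#' summaries (device x mode, pooled over participants and tasks), builds
#' the participants x conditions table of median TTI+Pre-TTI and runs the
#' statistical pipeline.  All outputs plus a provenance manifest are
#' written to `out_dir`; a failed session is logged and skipped, the study
#' continues.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (defaults to `config$out_dir`); created
#'   if missing.  Use `NULL` to skip writing files.
#' @param progress print per-session progress to stderr.
#' @return An object of class `study_report`: list with `metrics` (all
#'   per-trial rows), `summaries` (condition summary table),
#'   `rm_table` (participants x conditions medians), `stats`
#'   (a `stats_report` or `NULL`), `failures`, `manifest`.
#' @export
run_study <- function(config, out_dir = config$out_dir, progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  profiles <- study_profiles(config)
  say <- function(...) if (progress) message(...)
  all_metrics <- list()
  failures <- list()
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    say("participant ", prof$id, ": calibrating decoders")
    rv_run <- generate_calibration_eeg(prof, config$calib_trials,
                                       config$calib_trial_len,
                                       config$calib_iti,
                                       seed = derive_seed(prof$rng_seed, "rv"))
    fb_run <- generate_calibration_eeg(prof, config$calib_trials,
                                       config$calib_trial_len,
                                       config$calib_iti,
                                       seed = derive_seed(prof$rng_seed, "fb"))
    erd_cal <- erd_calibrate(rv_run, fb_run,
                             search_band = config$search_band,
                             ar_order = config$ar_order,
                             window_len = config$window_len,
                             step = config$step, dwell = config$dwell)
    hov_rec <- generate_hov_calibration_eog(
      prof, config$hov_movements,
      seed = derive_seed(prof$rng_seed, "hov"))
    hov_cal <- hov_calibrate(hov_rec)
    for (dev in config$devices) for (mode in config$modes)
      for (task in config$tasks) {
        say("participant ", prof$id, ": ", dev, "/", mode, "/", task)
        res <- tryCatch({
          plan <- session_plan(task, mode, dev, config$n_repetitions,
                               seed = derive_seed(prof$rng_seed, dev, mode,
                                                  task))
          sess <- generate_task_session(prof, plan)
          log <- run_task_session(sess, erd_cal, hov_cal)
          tm <- trial_metrics(log, sess$device)
          tm$participant <- prof$id
          tm$device <- dev
          tm$mode <- mode
          tm$task <- task
          tm
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            participant = prof$id, device = dev, mode = mode, task = task,
            error = conditionMessage(res))
          say("  FAILED: ", conditionMessage(res))
        } else {
          all_metrics[[length(all_metrics) + 1L]] <- res
        }
      }
  }
  if (!length(all_metrics)) stop("no session produced any metrics")
  metrics <- do.call(rbind, all_metrics)

  conds <- expand.grid(device = config$devices, mode = config$modes,
                       stringsAsFactors = FALSE)
  summaries <- do.call(rbind, lapply(seq_len(nrow(conds)), function(k) {
    sel <- metrics$device == conds$device[k] & metrics$mode == conds$mode[k]
    s <- summarize_condition(metrics[sel, , drop = FALSE])
    data.frame(device = conds$device[k], mode = conds$mode[k],
               median = s$median, q25 = s$q25, q75 = s$q75,
               fluent = s$fluent, reliable = s$reliable,
               n_success = s$n_trials, n_total = s$n_total,
               success_rate = s$success_rate)
  }))

  keys <- mapply(condition_key, conds$device, conds$mode, USE.NAMES = FALSE)
  ids <- vapply(profiles, `[[`, character(1), "id")
  rm_table <- matrix(NA_real_, nrow = length(ids), ncol = nrow(conds),
                     dimnames = list(ids, keys))
  for (k in seq_len(nrow(conds))) for (id in ids) {
    sel <- metrics$participant == id & metrics$device == conds$device[k] &
      metrics$mode == conds$mode[k] & metrics$success
    if (any(sel))
      rm_table[id, k] <- stats::median(metrics$tti_plus_pre_tti[sel])
  }
  stats_rep <- NULL
  if (ncol(rm_table) >= 2L && sum(stats::complete.cases(rm_table)) >= 3L) {
    stats_rep <- tryCatch(stats_pipeline(rm_table), error = function(e) {
      say("statistics stage skipped: ", conditionMessage(e))
      NULL
    })
  } else {
    say("statistics stage skipped: too few complete participants")
  }

  report <- structure(list(metrics = metrics, summaries = summaries,
                           rm_table = rm_table, stats = stats_rep,
                           failures = if (length(failures))
                             do.call(rbind, failures) else NULL,
                           config = config, manifest = NULL),
                      class = "study_report")
  if (!is.null(out_dir)) report <- write_study_outputs(report, out_dir)
  report
}

write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("trial_metrics.csv", "condition_summaries.csv",
             "condition_summaries.json", "rm_table.csv", "stats.json")
  utils::write.csv(report$metrics,
                   file.path(out_dir, "trial_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summaries,
                   file.path(out_dir, "condition_summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summaries,
                       file.path(out_dir, "condition_summaries.json"),
                       digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(report$rm_table),
                   file.path(out_dir, "rm_table.csv"))
  stats_obj <- if (is.null(report$stats)) list() else
    list(normality = as.list(report$stats$normality),
         friedman = report$stats$friedman,
         pairwise = report$stats$pairwise,
         family = report$stats$family)
  jsonlite::write_json(stats_obj, file.path(out_dir, "stats.json"),
                       digits = NA, pretty = TRUE, auto_unbox = TRUE)
  cfg <- report$config
  cfg$participants <- NULL
  manifest <- list(
    package = "hybridbci",
    version = as.character(utils::packageVersion("hybridbci")),
    master_seed = cfg$master_seed,
    config = unclass(cfg),
    config_hash = fnv1a(paste(deparse(unclass(cfg)), collapse = "")),
    outputs = c(files, "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$manifest <- manifest
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d per-trial metric rows, %d failed session(s)\n",
              nrow(x$metrics),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  cat("  condition summaries (TTI+Pre-TTI, s):\n")
  print(x$summaries, row.names = FALSE)
  if (!is.null(x$stats))
    cat(sprintf("  Friedman: chi^2 = %.2f, p = %.3g\n",
                x$stats$friedman$statistic, x$stats$friedman$p_value))
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  if (!is.null(object$stats)) print(object$stats)
  invisible(object)
}
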