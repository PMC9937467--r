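# End-to-end orchestration: preprocess -> label -> template score ->
# features -> split/sweep (and LOSO) -> event-level evaluation.

#' Extract a gesture template from a preprocessed recording
#'
#' Cuts one labeled face-touch event out of a quantized recording; the six
#' channels become the template every sliding window is scored against.
#'
#' @param qrec a `quantized_recording` (the event must survive the full
#'   preprocessing chain, i.e. lie inside the recording).
#' @param start_s,end_s event bounds, s.
#' @return a [gesture_template()].
#' @export
select_template <- function(qrec, start_s, end_s) {
  stopifnot(inherits(qrec, "quantized_recording"))
  n <- nrow(qrec$accel_q)
  t <- (seq_len(n) - 1) / qrec$fs
  if (start_s < 0 || end_s > t[n] + 1e-9 || start_s >= end_s)
    stop_param("template event (", start_s, ", ", end_s,
               ") lies outside the recording")
  idx <- which(t >= start_s - 1e-9 & t <= end_s + 1e-9)
  gesture_template(cbind(qrec$accel_q[idx, , drop = FALSE],
                         qrec$gyro_q[idx, , drop = FALSE]),
                   fs = qrec$fs, steps = qrec$steps)
}

#' Score one session against the template and label its instants
#'
#' Runs [sliding_scores()] on all six quantized channels, assembles the 8-D
#' feature matrix and attaches per-instant labels.
#'
#' @param qrec a `quantized_recording`.
#' @param template a [gesture_template()].
#' @param labels a [label_vector()] at the quantized rate.
#' @param truth ground-truth [event_list()] used later for event-level
#'   evaluation.
#' @param cfg a [run_config()].
#' @return a session record: `list(subject_id, environment, fm, truth)`.
#' @export
extract_session_features <- function(qrec, template, labels, truth,
                                     cfg = run_config()) {
  window_samples <- round(cfg$window_s * qrec$fs)
  score1 <- function(x, tch) sliding_scores(
    x, tch, window_samples = window_samples,
    step_samples = cfg$step_samples, radius = cfg$fastdtw_radius,
    fs = qrec$fs)
  acc <- lapply(1:3, function(i) score1(qrec$accel_q[, i],
                                        template$channels[, i]))
  gyr <- lapply(1:3, function(i) score1(qrec$gyro_q[, i],
                                        template$channels[, i + 3]))
  fm <- build_features(acc, gyr, subject_id = qrec$subject_id,
                       environment = qrec$environment)
  fm <- attach_labels(fm, labels, window_samples, cfg$step_samples,
                      rule = cfg$label_rule)
  list(subject_id = qrec$subject_id, environment = qrec$environment,
       fm = fm, truth = truth)
}

# Preprocess and label every session of a cohort.  Gravity is estimated once
# per subject, from the rest window opening that subject's first session,
# and applied to all of the subject's trials.  Natural sessions are labeled
# from their log sheet (face touches only; entries whose refinement fails
# are collected and skipped); controlled sessions from their script.
prepare_sessions <- function(cohort, cfg, verbose = FALSE) {
  fs_ds <- cfg$fs / cfg$downsample_factor
  gravity <- list()
  failed <- list()
  out <- list()
  for (s in cohort$sessions) {
    filt <- lowpass_filter(s$recording, cfg$cutoff_hz, cfg$filter_order)
    if (is.null(gravity[[s$subject_id]]))
      gravity[[s$subject_id]] <- estimate_gravity(filt, c(0, cfg$rest_s))
    rec <- vertical_align(filt, gravity[[s$subject_id]])
    rec <- downsample(rec, cfg$downsample_factor, antialias = cfg$antialias)
    qrec <- quantize(rec, cfg$accel_step, cfg$gyro_step)
    if (s$environment == "natural") {
      # refine on the filtered full-rate signal (|gyro| is rotation-invariant)
      lab <- label_from_logsheet(filt, s$logsheet,
                                 half_window = cfg$half_window_s,
                                 smooth_s = cfg$smooth_s,
                                 min_prominence = cfg$min_prominence,
                                 max_span_s = cfg$max_span_s,
                                 on_error = "skip")
      if (length(attr(lab$events, "failed_entries")))
        failed[[s$subject_id]] <- attr(lab$events, "failed_entries")
      label_events <- lab$events
      truth <- s$truth[s$truth$class == 1L, , drop = FALSE]
    } else {
      label_events <- s$truth
      truth <- s$truth
    }
    labels <- labels_from_events(label_events, nrow(qrec$accel_q), fs_ds)
    out[[length(out) + 1L]] <- list(subject_id = s$subject_id,
                                    environment = s$environment,
                                    qrec = qrec, labels = labels,
                                    truth = truth)
    if (verbose)
      message(sprintf("preprocessed %s/%s: %d samples -> %d @ %g Hz",
                      s$subject_id, s$environment,
                      n_samples(s$recording), nrow(qrec$accel_q), fs_ds))
  }
  attr(out, "failed_refinements") <- failed
  out
}

# Event-level confusion counts for one environment's test predictions.
# Instants are grouped per session (subject); RP/RN count the truth events
# exposed to the test set, i.e. those containing at least one test-set
# window centre.
evaluate_split <- function(test_fm, pred_pos, sessions, cfg, fs_ds) {
  window_samples <- round(cfg$window_s * fs_ds)
  half_s <- (window_samples %/% 2) / fs_ds
  tot <- c(RP = 0L, RN = 0L, TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (s in sessions) {
    rows <- which(test_fm$subject_id == s$subject_id)
    if (!length(rows)) next
    times <- test_fm$instant_time[rows]
    centers <- times + half_s
    pred_ev <- instants_to_events(times, pred_pos[rows],
                                  window_s = cfg$window_s,
                                  merge_gap_s = cfg$merge_gap_s,
                                  min_event_s = cfg$min_event_s)
    exposed <- function(ev) {
      if (!nrow(ev)) return(ev)
      keep <- vapply(seq_len(nrow(ev)), function(i)
        any(centers >= ev$start_s[i] & centers <= ev$end_s[i]), logical(1))
      ev[keep, , drop = FALSE]
    }
    truth_face <- exposed(s$truth[s$truth$class == 1L, , drop = FALSE])
    negatives <- exposed(s$truth[s$truth$class == 2L, , drop = FALSE])
    cc <- match_events(pred_ev, truth_face, negatives)
    tot <- tot + unlist(cc)[names(tot)]
  }
  do.call(confusion_counts, as.list(tot))
}

#' Run the full detection experiment
#'
#' Simulates (or accepts) a cohort, preprocesses and labels every session,
#' selects the template, scores all sessions, and evaluates the randomized
#' 70/30 split over the k grid for each environment - optionally followed
#' by leave-one-subject-out cross-validation.  The run is a pure function
#' of (cohort, config, seed).
#'
#' @param cfg a [run_config()].
#' @param cohort a [simulate_cohort()] result; `NULL` simulates one with
#'   the config's seed and the generator defaults.
#' @param template a [gesture_template()]; `NULL` selects the first
#'   face-touch event of the first subject's controlled session.
#' @param run_loso also run LOSO cross-validation (slower).
#' @param verbose emit per-stage progress messages.
#' @return an object of class `run_report`: `config`, per-environment
#'   `counts` (per k) and metric `tables`, `loso` (or NULL), instant
#'   bookkeeping in `summary`, and `provenance`.
#' @export
run_experiment <- function(cfg = run_config(), cohort = NULL, template = NULL,
                           run_loso = FALSE, verbose = FALSE) {
  validate_config(cfg)
  if (is.null(cohort)) {
    if (verbose) message("simulating cohort (seed ", cfg$seed, ")")
    cohort <- simulate_cohort(seed = cfg$seed)
  }
  fs_ds <- cfg$fs / cfg$downsample_factor
  prep <- prepare_sessions(cohort, cfg, verbose = verbose)
  if (is.null(template)) {
    first_ctrl <- Filter(function(p) p$environment == "controlled", prep)[[1]]
    ev <- first_ctrl$truth[first_ctrl$truth$class == 1L, , drop = FALSE]
    if (!nrow(ev)) stop_param("no face-touch event available for the template")
    template <- select_template(first_ctrl$qrec, ev$start_s[1], ev$end_s[1])
  }
  sessions <- lapply(prep, function(p) {
    if (verbose) message("scoring ", p$subject_id, "/", p$environment)
    extract_session_features(p$qrec, template, p$labels, p$truth, cfg)
  })
  counts <- list(); tables <- list(); summary <- list()
  for (env in c("controlled", "natural")) {
    env_sessions <- Filter(function(s) s$environment == env, sessions)
    if (!length(env_sessions)) next
    fm <- do.call(rbind, lapply(env_sessions, `[[`, "fm"))
    summary[[env]] <- list(n_instants = nrow(fm),
                           n_face = sum(fm$label == 1L),
                           n_confounding = sum(fm$label == 2L))
    split <- split_train_test(fm, cfg$split_frac, cfg$seed)
    preds <- sweep_k(split$train, split$test, cfg$k_grid)
    cbk <- lapply(seq_along(cfg$k_grid), function(ki)
      evaluate_split(split$test, preds[, ki] == 1L, env_sessions, cfg, fs_ds))
    names(cbk) <- cfg$k_grid
    counts[[env]] <- cbk
    tables[[env]] <- report_table(cbk, mode = env)
    if (verbose)
      message(env, ": ", nrow(fm), " instants (",
              summary[[env]]$n_face, " face touch)")
  }
  loso <- NULL
  if (run_loso) {
    if (verbose) message("running LOSO cross-validation")
    loso <- loso_cv(sessions, k_grid = cfg$k_grid, window_s = cfg$window_s,
                    merge_gap_s = cfg$merge_gap_s,
                    min_event_s = cfg$min_event_s)
  }
  structure(list(config = cfg, counts = counts, tables = tables,
                 loso = loso, summary = summary,
                 failed_refinements = attr(prep, "failed_refinements"),
                 template_length = nrow(template$channels),
                 provenance = list(seed = cfg$seed,
                                   package_version =
                                     as.character(utils::packageVersion("facetouch")),
                                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "\n")
  for (env in names(x$tables)) {
    cat("\n==", env, "environment (70/30 split) ==\n")
    print(x$tables[[env]], row.names = FALSE)
  }
  if (!is.null(x$loso)) {
    cat("\n== LOSO averages per environment ==\n")
    avg <- x$loso$average
    avg[, -1] <- round_half_up(as.matrix(avg[, -1]))
    print(avg, row.names = FALSE)
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' `metrics.json` (counts + tables; byte-identical across reruns of the same
#' config and seed), per-environment CSV tables, the resolved config as
#' YAML, and `provenance.json`.
#'
#' @param report a [run_experiment()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list(
    counts = lapply(report$counts, function(cbk) lapply(cbk, unclass)),
    tables = report$tables, summary = report$summary)
  if (!is.null(report$loso))
    metrics$loso <- list(per_k = report$loso$per_k,
                         average = report$loso$average)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (env in names(report$tables))
    utils::write.csv(report$tables[[env]],
                     file.path(dir, paste0("table_", env, ".csv")),
                     row.names = FALSE)
  write_config(report$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
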