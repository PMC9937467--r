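# Seeded generator of labeled synthetic wrist-IMU sessions.
#
# A gesture is a minimum-jerk reach -> dwell -> return rotation of the wrist
# about a class-specific axis.  The gyroscope is the analytic derivative of
# the angle profile (two-lobed magnitude bracketing a quiet dwell - the
# signature the labeling stage relies on); the accelerometer sees
# sensor-frame gravity rotated by the orientation trajectory plus a scaled
# second derivative of the reach displacement and white Gaussian noise.
# Classes differ in excursion, duration, dwell fraction, oscillation
# (handwashing adds a sustained 2-4 Hz component, head scratching an
# oscillatory dwell, eating repeats small cycles) and axis mix.

mj  <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5   # minimum-jerk position
mjv <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4  # its velocity
mja <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3  # its acceleration

# Rodrigues rotation of vector v about unit axis u by each angle in deg.
rotate_vec_about <- function(axis, theta_deg, v) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  uv <- cross3(u, v)
  udv <- sum(u * v)
  outer(cos(th), v) + outer(sin(th), uv) + outer(1 - cos(th), udv * u)
}

rot_axis <- function(u, theta_deg) {
  u <- u / sqrt(sum(u^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Gesture-class kinematic parameters
#'
#' Per-class duration and excursion ranges, dwell fraction, oscillation and
#' rotation-axis mix, plus the sensor noise levels.  Units: seconds,
#' degrees, Hz, m/s^2 and deg/s.  The defaults are the study conditions the
#' rest of the package is exercised under; see the methods vignette for the
#' rationale behind each value.
#'
#' @param accel_noise_sd accelerometer noise, m/s^2.
#' @param gyro_noise_sd gyroscope noise, deg/s.
#' @param log_jitter_s half-width of the uniform log-sheet timing error, s.
#' @return a list of class `gesture_params`.
#' @export
gesture_params <- function(accel_noise_sd = 0.05, gyro_noise_sd = 1,
                           log_jitter_s = 2) {
  cl <- list(
    face_touch   = list(duration_range = c(2.2, 3.2),
                        excursion_range = c(70, 95), dwell_frac = 0.30,
                        osc_amp = 0, osc_freq_range = c(0, 0),
                        axis = c(1, 0.3, 0.1), repeats = 1L),
    drinking     = list(duration_range = c(3.5, 4.5),
                        excursion_range = c(55, 75), dwell_frac = 0.50,
                        osc_amp = 0, osc_freq_range = c(0, 0),
                        axis = c(1, -0.4, 0.2), repeats = 1L),
    eating       = list(duration_range = c(2.8, 4.2),
                        excursion_range = c(35, 50), dwell_frac = 0.20,
                        osc_amp = 0, osc_freq_range = c(0, 0),
                        axis = c(1, 0.1, -0.3), repeats = 2:3),
    scratch_head = list(duration_range = c(2.5, 4.0),
                        excursion_range = c(75, 100), dwell_frac = 0.45,
                        osc_amp = 12, osc_freq_range = c(3, 4.5),
                        axis = c(0.8, 0.5, -0.2), repeats = 1L),
    handwash     = list(duration_range = c(4.0, 6.0),
                        excursion_range = c(15, 25), dwell_frac = 0.60,
                        osc_amp = 30, osc_freq_range = c(2, 4),
                        axis = c(0.2, 1, 0.4), repeats = 1L),
    reach_pick   = list(duration_range = c(2.0, 3.0),
                        excursion_range = c(-60, -40), dwell_frac = 0.15,
                        osc_amp = 0, osc_freq_range = c(0, 0),
                        axis = c(0.4, -0.8, 0.4), repeats = 1L))
  for (p in cl) {
    stopifnot(all(p$duration_range > 0), p$dwell_frac >= 0, p$dwell_frac < 1)
  }
  structure(list(classes = cl, accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd, log_jitter_s = log_jitter_s),
            class = "gesture_params")
}

confounder_classes <- c("eating", "drinking", "scratch_head", "handwash",
                        "reach_pick")

#' Per-subject kinematic profile
#'
#' Multiplicative offsets on gesture duration and excursion (subject
#' individuality, enough to make leave-one-subject-out folds non-trivial)
#' and the mounting orientation of the wrist unit (rotation matrix from the
#' body-reference frame to the sensor frame's parent).
#'
#' @param dur_scale,exc_scale multiplicative offsets (1 = nominal).
#' @param R_mount 3 x 3 rotation describing how the band sits on the wrist.
#' @return a list of class `subject_profile` (includes the rest-gravity
#'   vector in the sensor frame).
#' @export
subject_profile <- function(dur_scale = 1, exc_scale = 1, R_mount = diag(3)) {
  R_t <- t(R_mount)
  structure(list(dur_scale = dur_scale, exc_scale = exc_scale,
                 R_mount_t = R_t, g_rest = drop(R_t %*% c(0, 0, 9.81))),
            class = "subject_profile")
}

# Band mounting varies mostly by roll about the forearm axis plus a small
# tilt; draws from the current RNG stream.
random_mount <- function(max_tilt_deg = 15) {
  roll <- rot_axis(c(1, 0, 0), runif(1, 0, 360))
  ax <- rnorm(3)
  tilt <- rot_axis(ax, runif(1, 0, max_tilt_deg))
  tilt %*% roll
}

# One reach-dwell-return cycle: angle (deg), angular speed (deg/s) and the
# scalar reach-acceleration profile (1/s^2, to be scaled by displacement).
reach_dwell_return <- function(dur, dwell_frac, exc, osc_amp, osc_freq, fs) {
  n <- max(8L, round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  T_d <- dwell_frac * dur
  T_r <- (dur - T_d) / 2
  theta <- numeric(n); omega <- numeric(n); lin <- numeric(n)
  ph1 <- t < T_r
  ph2 <- t >= T_r & t < T_r + T_d
  ph3 <- t >= T_r + T_d
  tau1 <- t[ph1] / T_r
  theta[ph1] <- exc * mj(tau1)
  omega[ph1] <- exc * mjv(tau1) / T_r
  lin[ph1] <- mja(tau1) / T_r^2
  td <- t[ph2] - T_r
  theta[ph2] <- exc + osc_amp * sin(2 * pi * osc_freq * td)
  omega[ph2] <- osc_amp * 2 * pi * osc_freq * cos(2 * pi * osc_freq * td)
  tau3 <- pmin(1, (t[ph3] - T_r - T_d) / T_r)
  theta[ph3] <- exc * (1 - mj(tau3))
  omega[ph3] <- -exc * mjv(tau3) / T_r
  lin[ph3] <- -mja(tau3) / T_r^2
  list(theta = theta, omega = omega, lin = lin)
}

#' Simulate one gesture (or rest) segment
#'
#' @param class one of `"face_touch"`, `"eating"`, `"drinking"`,
#'   `"scratch_head"`, `"handwash"`, `"reach_pick"`, or `"rest"`.
#' @param params a [gesture_params()].
#' @param fs sampling rate, Hz.
#' @param subject a [subject_profile()].
#' @param duration_s rest duration (rest segments only).
#' @param seed optional seed; when `NULL` the segment is drawn from the
#'   current RNG stream (as [simulate_session()] does).
#' @return list with `accel` (N x 3, m/s^2, gravity included), `gyro`
#'   (N x 3, deg/s), `duration_s`, `class` and the event `label`
#'   (1 face touch, 2 confounding, 0 rest).
#' @export
simulate_gesture <- function(class, params = gesture_params(), fs = 128,
                             subject = subject_profile(), duration_s = 5,
                             seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(as.integer(seed),
      simulate_gesture(class, params, fs, subject, duration_s)))
  if (class == "rest") {
    n <- max(2L, round(duration_s * fs))
    accel <- matrix(rep(subject$g_rest, each = n), n) +
      matrix(rnorm(3 * n, 0, params$accel_noise_sd), n)
    gyro <- matrix(rnorm(3 * n, 0, params$gyro_noise_sd), n)
    return(list(accel = accel, gyro = gyro, duration_s = n / fs,
                class = class, label = 0L))
  }
  if (!class %in% names(params$classes)) stop_param("unknown class: ", class)
  p <- params$classes[[class]]
  dur <- runif(1, p$duration_range[1], p$duration_range[2]) * subject$dur_scale
  exc <- runif(1, p$excursion_range[1], p$excursion_range[2]) * subject$exc_scale
  osc_f <- if (p$osc_amp > 0) runif(1, p$osc_freq_range[1], p$osc_freq_range[2]) else 0
  reps <- if (length(p$repeats) > 1) sample(p$repeats, 1) else p$repeats
  segs <- lapply(seq_len(reps), function(i)
    reach_dwell_return(dur / reps, p$dwell_frac, exc, p$osc_amp, osc_f, fs))
  theta <- unlist(lapply(segs, `[[`, "theta"))
  omega <- unlist(lapply(segs, `[[`, "omega"))
  lin <- unlist(lapply(segs, `[[`, "lin"))
  n <- length(theta)

  axis <- p$axis + rnorm(3, 0, 0.05)
  axis_s <- drop(subject$R_mount_t %*% (axis / sqrt(sum(axis^2))))
  gyro <- outer(omega, axis_s) +
    matrix(rnorm(3 * n, 0, params$gyro_noise_sd), n)
  grav <- rotate_vec_about(axis_s, -theta, subject$g_rest)
  disp <- runif(1, 0.25, 0.45) * abs(exc) / 90     # reach amplitude, m
  lin_dir <- rnorm(3); lin_dir <- lin_dir / sqrt(sum(lin_dir^2))
  accel <- grav + outer(disp * lin, lin_dir) +
    matrix(rnorm(3 * n, 0, params$accel_noise_sd), n)
  list(accel = accel, gyro = gyro, duration_s = n / fs, class = class,
       label = if (class == "face_touch") 1L else 2L)
}

#' Simulate one labeled session
#'
#' Gestures (face touches plus confounders) in shuffled order, separated by
#' rest gaps, with 10 s of rest at the start and end.  The ground-truth
#' event list is exact; the log sheet holds each face-touch midpoint
#' perturbed by uniform timing error (natural-environment self reporting).
#'
#' @param subject_id subject identifier.
#' @param environment `"controlled"` or `"natural"`.
#' @param n_face number of face touches.
#' @param confounders_per_class named integer vector of confounding-gesture
#'   counts (names from `"eating"`, `"drinking"`, `"scratch_head"`,
#'   `"handwash"`, `"reach_pick"`).
#' @param duration_s total session length, s; `NULL` (controlled default)
#'   lets the schedule dictate it, a fixed value (natural default 1200)
#'   spreads the remaining time over random rest gaps.
#' @param gap_range rest-gap range between gestures, s (minimum also applies
#'   to the random gaps of fixed-duration sessions).
#' @param params a [gesture_params()].
#' @param subject a [subject_profile()].
#' @param fs sampling rate, Hz.
#' @param seed optional seed; `NULL` draws from the current stream.
#' @return a list of class `synthetic_session`: `recording`
#'   ([imu_recording()]), `truth` ([event_list()]), `logsheet`
#'   ([log_sheet()], face touches only), `subject_id`, `environment`.
#' @export
simulate_session <- function(subject_id = "S01",
                             environment = c("controlled", "natural"),
                             n_face = 5,
                             confounders_per_class = c(eating = 2, drinking = 2,
                                                       scratch_head = 2,
                                                       handwash = 2,
                                                       reach_pick = 2),
                             duration_s = NULL, gap_range = c(3, 5),
                             params = gesture_params(),
                             subject = subject_profile(), fs = 128,
                             seed = NULL) {
  environment <- match.arg(environment)
  if (!is.null(seed))
    return(withr::with_seed(as.integer(seed), simulate_session(
      subject_id, environment, n_face, confounders_per_class, duration_s,
      gap_range, params, subject, fs)))
  stopifnot(all(names(confounders_per_class) %in% confounder_classes))
  classes <- c(rep("face_touch", n_face),
               rep(names(confounders_per_class), confounders_per_class))
  if (length(classes)) classes <- sample(classes)
  gests <- lapply(classes, simulate_gesture, params = params, fs = fs,
                  subject = subject)
  g_dur <- vapply(gests, `[[`, numeric(1), "duration_s")
  n_g <- length(classes)
  n_gaps <- n_g + 1L
  mid <- max(0L, n_g - 1L)
  if (is.null(duration_s)) {
    mids <- if (mid) runif(mid, gap_range[1], gap_range[2]) else numeric()
    gaps <- if (n_g == 0) 20 else c(10, mids, 10)
  } else {
    slack <- duration_s - 20 - sum(g_dur) - gap_range[1] * mid
    if (slack < 0)
      stop_param("infeasible schedule: ", n_g,
                 " gestures do not fit in ", duration_s, " s")
    if (n_g == 0) {
      gaps <- duration_s
    } else if (mid == 0) {
      gaps <- c(10, 10 + slack)
    } else {
      u <- runif(mid)
      gaps <- c(10, gap_range[1] + slack * (u / sum(u)), 10)
    }
  }
  segs <- list(); starts <- numeric(length(classes)); t0 <- 0
  for (i in seq_along(classes)) {
    segs[[length(segs) + 1L]] <- simulate_gesture(
      "rest", params, fs, subject, duration_s = gaps[i])
    t0 <- t0 + segs[[length(segs)]]$duration_s
    starts[i] <- t0
    segs[[length(segs) + 1L]] <- gests[[i]]
    t0 <- t0 + g_dur[i]
  }
  segs[[length(segs) + 1L]] <- simulate_gesture(
    "rest", params, fs, subject, duration_s = gaps[n_gaps])
  accel <- do.call(rbind, lapply(segs, `[[`, "accel"))
  gyro <- do.call(rbind, lapply(segs, `[[`, "gyro"))
  rec <- imu_recording(accel, gyro, fs = fs, subject_id = subject_id,
                       environment = environment)
  truth <- if (length(classes))
    event_list(starts, starts + g_dur,
               ifelse(classes == "face_touch", 1L, 2L))
  else event_list()
  mid <- starts[classes == "face_touch"] + g_dur[classes == "face_touch"] / 2
  jit <- if (length(mid)) runif(length(mid), -params$log_jitter_s,
                                params$log_jitter_s) else numeric()
  logs <- log_sheet(pmin(pmax(mid + jit, 0), duration_s(rec)),
                    rep("face touch", length(mid)))
  structure(list(recording = rec, truth = truth, logsheet = logs,
                 subject_id = subject_id, environment = environment,
                 gesture_classes = classes),
            class = "synthetic_session")
}

#' Simulate a multi-subject cohort
#'
#' One controlled and one natural session per subject.  Controlled sessions
#' script `controlled_reps` repetitions of the face touch and of each of the
#' five confounding gestures; natural sessions are 20 minutes of rest-
#' dominated activity containing `natural_n_face` face touches and
#' `natural_conf_each` of each confounder, logged with timing jitter.
#' Per-subject kinematic offsets (duration/excursion within +/-20%) and
#' band-mounting orientations are drawn once per subject.
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed; the whole cohort is a deterministic function of it.
#' @param params a [gesture_params()].
#' @param controlled_reps repetitions per gesture class, controlled session.
#' @param natural_n_face face touches per natural session.
#' @param natural_conf_each confounders of each class per natural session.
#' @param natural_duration_s natural session length, s.
#' @param fs sampling rate, Hz.
#' @return a list of class `synthetic_cohort`: `sessions` (list of
#'   `synthetic_session`, controlled then natural per subject) and
#'   `profiles` (per-subject [subject_profile()]s).
#' @export
simulate_cohort <- function(n_subjects = 11, seed = 42,
                            params = gesture_params(), controlled_reps = 25,
                            natural_n_face = 5, natural_conf_each = 2,
                            natural_duration_s = 1200, fs = 128) {
  if (n_subjects < 1) stop_param("n_subjects must be >= 1")
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("S%02d", seq_len(n_subjects))
    profiles <- lapply(ids, function(id)
      subject_profile(dur_scale = runif(1, 0.8, 1.2),
                      exc_scale = runif(1, 0.8, 1.2),
                      R_mount = random_mount()))
    names(profiles) <- ids
    sessions <- list()
    for (i in seq_len(n_subjects)) {
      conf_c <- stats::setNames(rep(controlled_reps, 5), confounder_classes)
      sessions[[length(sessions) + 1L]] <- simulate_session(
        ids[i], "controlled", n_face = controlled_reps,
        confounders_per_class = conf_c, duration_s = NULL,
        gap_range = c(2.5, 4.5), params = params, subject = profiles[[i]],
        fs = fs)
      conf_n <- stats::setNames(rep(natural_conf_each, 5), confounder_classes)
      sessions[[length(sessions) + 1L]] <- simulate_session(
        ids[i], "natural", n_face = natural_n_face,
        confounders_per_class = conf_n, duration_s = natural_duration_s,
        gap_range = c(3, 5), params = params, subject = profiles[[i]],
        fs = fs)
    }
    structure(list(sessions = sessions, profiles = profiles),
              class = "synthetic_cohort")
  })
}

#' Write a simulated cohort to disk
#'
#' One recording CSV, truth-event CSV and (natural sessions) log-sheet CSV
#' per session, plus a `manifest.csv` mapping files to subject and
#' environment.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the manifest `data.frame`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$sessions, function(s) {
    stem <- paste0(s$subject_id, "_", s$environment)
    write_recording(s$recording, file.path(dir, paste0(stem, ".csv")))
    write_events(s$truth, file.path(dir, paste0(stem, "_events.csv")))
    log_file <- NA_character_
    if (s$environment == "natural") {
      log_file <- paste0(stem, "_log.csv")
      write_logsheet(s$logsheet, file.path(dir, log_file))
    }
    data.frame(subject = s$subject_id, environment = s$environment,
               recording = paste0(stem, ".csv"),
               events = paste0(stem, "_events.csv"), log = log_file)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
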