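# Domain containers and plain-text readers/writers for wrist-IMU sessions.
#
# Canonical internal units are m/s^2 (acceleration) and deg/s (angular
# velocity); time is 0-based seconds on a uniform grid.  Events are closed
# intervals in seconds.

#' Construct a wrist-IMU recording
#'
#' One trial of tri-axial acceleration and angular velocity sampled on a
#' uniform grid.  Times are derived from `fs` and never stored redundantly.
#'
#' @param accel N x 3 numeric matrix of acceleration in m/s^2.
#' @param gyro N x 3 numeric matrix of angular velocity in deg/s.
#' @param fs sampling rate in Hz (the sensor used throughout records at 128).
#' @param subject_id subject identifier string.
#' @param environment `"controlled"` (scripted gesture scenarios) or
#'   `"natural"` (free daily-life activity with a self-reported log sheet).
#' @return an object of class `imu_recording` with fields `accel`, `gyro`,
#'   `fs`, `t` (sample times in s), `subject_id`, `environment`.
#' @export
imu_recording <- function(accel, gyro, fs = 128, subject_id = "S01",
                          environment = c("controlled", "natural")) {
  environment <- match.arg(environment)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (!is_scalar_num(fs) || fs <= 0) stop_param("fs must be a positive number")
  if (ncol(accel) != 3 || ncol(gyro) != 3)
    stop_format("accel and gyro must have 3 columns")
  if (nrow(accel) != nrow(gyro))
    stop_format("accel and gyro must have identical length")
  if (nrow(accel) < 2) stop_format("a recording needs at least 2 samples")
  bad <- which(!is.finite(accel) | !is.finite(gyro))
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(accel)) + 1
    stop_format("non-finite sensor value at row ", row)
  }
  dimnames(accel) <- list(NULL, c("acc_x", "acc_y", "acc_z"))
  dimnames(gyro) <- list(NULL, c("gyr_x", "gyr_y", "gyr_z"))
  structure(
    list(subject_id = subject_id, fs = fs,
         t = seq(0, by = 1 / fs, length.out = nrow(accel)),
         accel = accel, gyro = gyro, environment = environment),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s (%s): %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$environment, nrow(x$accel), x$fs,
              nrow(x$accel) / x$fs))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$accel)
duration_s <- function(rec) (n_samples(rec) - 1) / rec$fs

#' Construct an event list
#'
#' Labeled time intervals: class 1 = face touch, class 2 = confounding
#' gesture (eating, drinking, head scratching, handwashing, reach/pick).
#' Events are closed intervals; same-class events must not overlap; the list
#' is kept sorted by start time.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param class integer vector of class codes in \{1, 2\}.
#' @return a `data.frame` of class `event_list` with columns `start_s`,
#'   `end_s`, `class`.
#' @export
event_list <- function(start_s = numeric(), end_s = numeric(),
                       class = integer()) {
  if (length(start_s) != length(end_s) || length(start_s) != length(class))
    stop_format("start_s, end_s and class must have equal length")
  class <- as.integer(class)
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   class = class)
  if (nrow(df)) {
    if (any(!is.finite(df$start_s)) || any(!is.finite(df$end_s)))
      stop_format("event bounds must be finite")
    bad <- which(df$start_s >= df$end_s)
    if (length(bad)) stop_format("event ", bad[1], ": start_s >= end_s")
    if (!all(df$class %in% c(1L, 2L)))
      stop_format("event class must be 1 (face touch) or 2 (confounding)")
    df <- df[order(df$start_s, df$end_s), , drop = FALSE]
    rownames(df) <- NULL
    for (cl in unique(df$class)) {
      e <- df[df$class == cl, , drop = FALSE]
      if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)]))
        stop_format("overlapping events of class ", cl)
    }
  }
  structure(df, class = c("event_list", "data.frame"))
}

#' Construct a self-reported log sheet
#'
#' Approximate instants at which the wearer noted a face touch, used to label
#' natural-environment trials.
#'
#' @param approx_time_s numeric vector of approximate touch instants (s).
#' @param note optional character vector of free-text notes.
#' @return a `data.frame` of class `log_sheet`.
#' @export
log_sheet <- function(approx_time_s = numeric(), note = NULL) {
  note <- note %||% rep("", length(approx_time_s))
  if (length(note) != length(approx_time_s))
    stop_format("note must match approx_time_s in length")
  if (any(approx_time_s < 0)) stop_format("log times must be non-negative")
  df <- data.frame(approx_time_s = as.numeric(approx_time_s),
                   note = as.character(note), stringsAsFactors = FALSE)
  df <- df[order(df$approx_time_s), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("log_sheet", "data.frame"))
}

rec_columns <- c("time_s", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

#' Read a recording CSV
#'
#' Expects columns `time_s,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z`.  The time
#' column must be a uniform grid (step tolerance 1e-6 s); its step defines
#' the sampling rate.  Unit conversion from g / rad/s is applied when
#' requested.
#'
#' @param path CSV file path.
#' @param accel_unit `"ms2"` (default) or `"g"`.
#' @param gyro_unit `"degs"` (default) or `"rads"`.
#' @param gravity conversion factor used when `accel_unit = "g"`.
#' @param subject_id,environment recording metadata (see [imu_recording()]).
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, accel_unit = c("ms2", "g"),
                           gyro_unit = c("degs", "rads"), gravity = 9.81,
                           subject_id = "S01",
                           environment = c("controlled", "natural")) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  environment <- match.arg(environment)
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- data.table::fread(path, sep = ",", data.table = FALSE)
  missing_cols <- setdiff(rec_columns, names(df))
  if (length(missing_cols))
    stop_format("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (cn in rec_columns) {
    if (!is.numeric(df[[cn]]))
      stop_format("column ", cn, " is not numeric")
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad))
      stop_format("non-finite value in column ", cn, " at row ", bad[1])
  }
  if (nrow(df) < 2) stop_format("a recording needs at least 2 samples")
  dt <- diff(df$time_s)
  if (any(abs(dt - dt[1]) > 1e-6))
    stop_format("non-uniform time step at row ",
                which(abs(dt - dt[1]) > 1e-6)[1] + 1)
  if (dt[1] <= 0) stop_format("time_s must be strictly increasing")
  accel <- as.matrix(df[, c("acc_x", "acc_y", "acc_z")])
  gyro <- as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")])
  if (accel_unit == "g") accel <- accel * gravity
  if (gyro_unit == "rads") gyro <- gyro * 180 / pi
  imu_recording(accel, gyro, fs = 1 / dt[1], subject_id = subject_id,
                environment = environment)
}

#' Write a recording CSV
#'
#' Full double precision, so that `read_recording(write_recording(rec))`
#' reproduces `rec` to 1e-9 relative tolerance.
#'
#' @param rec an [imu_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(time_s = rec$t, rec$accel, rec$gyro)
  names(df) <- rec_columns
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read / write event CSVs
#'
#' Event files have columns `start_s,end_s,class`.  Rows may be unordered in
#' the file; the reader sorts and validates them (overlapping same-class rows
#' are a format error).
#'
#' @param path CSV file path.
#' @return [read_events()] returns an [event_list()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("start_s", "end_s", "class")
  if (!all(need %in% names(df)))
    stop_format("event file must have columns start_s,end_s,class")
  event_list(df$start_s, df$end_s, df$class)
}

#' @rdname read_events
#' @param events an [event_list()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read / write log-sheet CSVs (`approx_time_s,note`)
#'
#' @param path CSV file path.
#' @return [read_logsheet()] returns a [log_sheet()].
#' @export
read_logsheet <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- utils::read.csv(path)
  if (!"approx_time_s" %in% names(df))
    stop_format("log sheet must have a column approx_time_s")
  if (!is.numeric(df$approx_time_s))
    stop_format("approx_time_s must be numeric")
  note <- if ("note" %in% names(df)) as.character(df$note) else NULL
  log_sheet(df$approx_time_s, note)
}

#' @rdname read_logsheet
#' @param log a [log_sheet()].
#' @export
write_logsheet <- function(log, path) {
  stopifnot(inherits(log, "log_sheet"))
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
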