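# Assembly of the 8-dimensional DTW feature space and instant labels.
#
# Columns f1-f3: DTW scores of the three acceleration channels against the
# template; f4-f6: the three angular-velocity channels; f7 and f8: the means
# of the acceleration and of the angular-velocity scores (added to temper
# the per-channel sensitivity of the classifier).

feature_cols <- c("f1", "f2", "f3", "f4", "f5", "f6", "f7", "f8")

#' Build the 8-D feature matrix from six score series
#'
#' @param acc_scores list of three [sliding_scores()] results for the
#'   acceleration channels (x, y, z order).
#' @param gyro_scores list of three [sliding_scores()] results for the
#'   angular-velocity channels (x, y, z order).
#' @param subject_id,environment metadata carried into the matrix.
#' @return a `data.frame` of class `feature_matrix` with columns
#'   `instant_time`, `f1`..`f8`, `label` (NA until [attach_labels()]),
#'   `subject_id`, `environment`.
#' @export
build_features <- function(acc_scores, gyro_scores, subject_id = "S01",
                           environment = "controlled") {
  ser <- c(acc_scores, gyro_scores)
  if (length(ser) != 6 || !all(vapply(ser, inherits, logical(1), "dtw_score_series")))
    stop_format("need 3 acceleration and 3 angular-velocity score series")
  grid <- ser[[1]]$instant_times
  for (s in ser[-1]) {
    if (length(s$instant_times) != length(grid) ||
        any(abs(s$instant_times - grid) > 1e-9))
      stop_format("score series are not on the same instant grid")
  }
  X <- vapply(ser, `[[`, numeric(length(grid)), "scores")
  X <- matrix(X, ncol = 6)
  df <- data.frame(instant_time = grid,
                   f1 = X[, 1], f2 = X[, 2], f3 = X[, 3],
                   f4 = X[, 4], f5 = X[, 5], f6 = X[, 6])
  df$f7 <- (df$f1 + df$f2 + df$f3) / 3
  df$f8 <- (df$f4 + df$f5 + df$f6) / 3
  df$label <- NA_integer_
  df$subject_id <- subject_id
  df$environment <- environment
  attr(df, "window_s") <- ser[[1]]$window_s
  attr(df, "step_samples") <- ser[[1]]$step_samples
  attr(df, "fs") <- ser[[1]]$fs
  structure(df, class = c("feature_matrix", "data.frame"))
}

#' Attach per-instant class labels to a feature matrix
#'
#' An instant (one sliding-window position) inherits the label of the sample
#' at the window's centre, `start + window_samples / 2` (the default); the
#' `"majority"` rule instead takes the most frequent label inside the
#' window, ties to the lower class code.  Events shorter than the step may
#' yield no positive instant under the centre rule; this is accepted
#' behaviour.
#'
#' @param fm a [build_features()] result.
#' @param lv a [label_vector()] at the same rate as the scored series.
#' @param window_samples,step_samples the sliding-window geometry used for
#'   scoring.
#' @param rule `"center"` or `"majority"`.
#' @return `fm` with its `label` column filled.
#' @export
attach_labels <- function(fm, lv, window_samples = 96, step_samples = 6,
                          rule = c("center", "majority")) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(lv, "label_vector"))
  rule <- match.arg(rule)
  fs <- attr(lv, "fs")
  starts <- round(fm$instant_time * fs) + 1L
  if (max(starts) + window_samples - 1L > length(lv))
    stop_format("label vector does not cover the scored windows")
  if (rule == "center") {
    fm$label <- as.integer(lv[starts + window_samples %/% 2L])
  } else {
    fm$label <- vapply(starts, function(s) {
      tab <- tabulate(lv[s:(s + window_samples - 1L)] + 1L, nbins = 3L)
      as.integer(which.max(tab) - 1L)
    }, integer(1))
  }
  fm
}

#' Read / write feature matrices as CSV
#'
#' Header: `f1..f8,label,subject,environment,instant_time`.
#'
#' @param path CSV file path.
#' @return [read_features()] returns a `feature_matrix`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c(feature_cols, "label", "subject", "environment", "instant_time")
  if (!all(need %in% names(df)))
    stop_format("feature file must have columns ",
                paste(need, collapse = ","))
  out <- data.frame(instant_time = df$instant_time, df[, feature_cols],
                    label = as.integer(df$label), subject_id = df$subject,
                    environment = df$environment)
  structure(out, class = c("feature_matrix", "data.frame"))
}

#' @rdname read_features
#' @param fm a `feature_matrix`.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- data.frame(fm[, feature_cols], label = fm$label,
                    subject = fm$subject_id, environment = fm$environment,
                    instant_time = fm$instant_time)
  data.table::fwrite(out, path)
  invisible(path)
}
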