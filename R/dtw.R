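# Dynamic time warping: exact DP, the multilevel FastDTW approximation and
# sliding-window template scoring.  The DP kernels live in src/dtw_knn.cpp;
# these wrappers validate inputs and carry the domain containers.

#' Exact dynamic time warping score
#'
#' Full cost-matrix dynamic program with local cost `|a_i - b_j|`, the
#' symmetric step pattern (match / insert / delete, each weight 1) and
#' boundary-anchored paths from (1,1) to (n,m).  On quantized integer series
#' the score is integral.  Scores are not length-normalized.
#'
#' @param a,b numeric series (non-empty).
#' @return the minimal cumulative cost (non-negative scalar).
#' @examples
#' dtw_exact(c(0, 1), c(0, 1, 1))  # 0: the repeated 1 is absorbed by warping
#' @export
dtw_exact <- function(a, b) {
  if (!length(a) || !length(b)) stop_param("DTW requires non-empty series")
  dtw_exact_cpp(as.numeric(a), as.numeric(b))
}

#' FastDTW approximate score
#'
#' Multilevel approximation: the series are coarsened by pairwise averaging
#' (odd tail carried through), the coarse problem is solved recursively, the
#' coarse path is projected onto the fine grid and widened by `radius`, and
#' a constrained DP runs inside that corridor.  Series shorter than
#' `radius + 2` are solved exactly.  The result is the cost of a valid
#' warping path, hence always `>= dtw_exact(a, b)`, with equality guaranteed
#' when the radius spans the whole matrix.
#'
#' @param a,b numeric series (non-empty).
#' @param radius corridor radius (>= 0); 1 is the canonical setting.
#' @return approximate DTW score (non-negative scalar).
#' @export
fastdtw <- function(a, b, radius = 1) {
  if (!length(a) || !length(b)) stop_param("DTW requires non-empty series")
  if (!is_scalar_num(radius) || radius < 0 || radius != round(radius))
    stop_param("radius must be a non-negative integer")
  fastdtw_cpp(as.numeric(a), as.numeric(b), as.integer(radius))
}

#' Face-touch gesture template
#'
#' A single preprocessed exemplar of a face touch: six quantized channels
#' (acc x/y/z, gyr x/y/z) at the down-sampled rate.
#'
#' @param channels L x 6 integer matrix with columns
#'   `acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`.
#' @param fs sampling rate of the template, Hz.
#' @param steps named quantization steps `c(accel =, gyro =)` used to build
#'   the template (metadata only).
#' @return an object of class `gesture_template`.
#' @export
gesture_template <- function(channels, fs = 32, steps = c(accel = 0.5, gyro = 5)) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 6) stop_format("a template has 6 channels")
  if (nrow(channels) < 8) stop_format("a template needs at least 8 samples")
  if (any(channels != round(channels)))
    stop_format("template channels must be integer-valued")
  colnames(channels) <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  structure(list(channels = channels, fs = fs,
                 duration_s = (nrow(channels) - 1) / fs, steps = steps),
            class = "gesture_template")
}

#' Read / write a gesture template
#'
#' The template is stored as a 6-column CSV of integer levels plus a JSON
#' sidecar (`<path>.json`) carrying the sampling rate and quantization steps.
#'
#' @param path CSV file path.
#' @return [read_template()] returns a [gesture_template()].
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(fs = 32, steps = c(accel = 0.5, gyro = 5))
  ch <- as.matrix(utils::read.csv(path))
  gesture_template(ch, fs = meta$fs,
                   steps = c(accel = meta$steps[["accel"]],
                             gyro = meta$steps[["gyro"]]))
}

#' @rdname read_template
#' @param template a [gesture_template()].
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "gesture_template"))
  utils::write.csv(template$channels, path, row.names = FALSE)
  jsonlite::write_json(list(fs = template$fs, steps = as.list(template$steps)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Sliding-window DTW scores of one channel against a template channel
#'
#' Scores every 3-s window position of a quantized channel against the
#' corresponding template channel with FastDTW.  Window starts advance by
#' `step_samples`; the number of instants is
#' `floor((N - window_samples) / step_samples) + 1`.
#'
#' @param channel numeric (quantized) series at the down-sampled rate.
#' @param template_channel the matching template channel.
#' @param window_samples window length in samples (96 = 3 s at 32 Hz).
#' @param step_samples step between window starts in samples (6 = 0.1875 s
#'   at 32 Hz, the integer-grid rendering of a 0.2-s step).
#' @param radius FastDTW corridor radius.
#' @param fs sampling rate of `channel`, Hz (grid bookkeeping only).
#' @return an object of class `dtw_score_series`: `instant_times` (window
#'   start times, s), `scores`, `window_s`, `step_samples`, `fs`.
#' @export
sliding_scores <- function(channel, template_channel, window_samples = 96,
                           step_samples = 6, radius = 1, fs = 32) {
  if (length(channel) < window_samples)
    stop_param("series (", length(channel),
               ") shorter than one window (", window_samples, ")")
  sc <- sliding_scores_cpp(as.numeric(channel), as.numeric(template_channel),
                           as.integer(window_samples),
                           as.integer(step_samples), as.integer(radius))
  structure(list(instant_times = (seq_along(sc) - 1) * step_samples / fs,
                 scores = sc, window_s = window_samples / fs,
                 step_samples = as.integer(step_samples), fs = fs),
            class = "dtw_score_series")
}
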