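# Run configuration: every tunable of the pipeline in one validated list.

#' Pipeline run configuration
#'
#' Collects all tunables of the detection pipeline with their defaults.
#' Defaults replicate the published processing chain where it is stated
#' (128 Hz input, 30 Hz zero-phase Butterworth, down-sampling to 32 Hz,
#' 3-s window, ~0.2-s step, k = 3..21 odd, 70/30 split) and this package's
#' documented choices where it is not (quantization steps, merge/min event
#' durations, labeling search parameters).
#'
#' @param fs input sampling rate, Hz.
#' @param cutoff_hz low-pass cut-off, Hz; must be below `fs / 2`.
#' @param filter_order Butterworth design order applied forward-backward
#'   (3 gives an effective 6th-order zero-phase response).
#' @param rest_s duration of the quiet rest window at the start of a
#'   subject's first trial used for gravity estimation, s.
#' @param downsample_factor integer decimation factor (128 -> 32 Hz).
#' @param antialias apply an extra 12 Hz anti-alias filter before
#'   decimation (off by default, replicating the published chain).
#' @param accel_step,gyro_step quantization steps, m/s^2 and deg/s.
#' @param window_s sliding-window length, s.
#' @param step_samples sliding-window step, samples at the down-sampled rate
#'   (6 samples = 0.1875 s, the integer-grid rendering of a 0.2-s step).
#' @param fastdtw_radius FastDTW corridor radius.
#' @param k_grid KNN neighbour counts to sweep.
#' @param split_frac training fraction of the randomized instant split.
#' @param seed RNG seed for simulation and splitting.
#' @param half_window_s,smooth_s,min_prominence,max_span_s log-sheet
#'   refinement parameters (see [refine_touch_event()]).
#' @param merge_gap_s,min_event_s predicted-event merging parameters (see
#'   [instants_to_events()]).
#' @param label_rule instant labeling rule, `"center"` (default) or
#'   `"majority"`.
#' @param accel_unit,gyro_unit,gravity input units for [read_recording()].
#' @return a named list of class `run_config`.
#' @export
run_config <- function(fs = 128, cutoff_hz = 30, filter_order = 3,
                       rest_s = 10, downsample_factor = 4, antialias = FALSE,
                       accel_step = 0.5, gyro_step = 5,
                       window_s = 3, step_samples = 6, fastdtw_radius = 1,
                       k_grid = seq(3L, 21L, by = 2L), split_frac = 0.7,
                       seed = 42L,
                       half_window_s = 5, smooth_s = 0.25,
                       min_prominence = 10, max_span_s = 3,
                       merge_gap_s = 0.4, min_event_s = 0.5,
                       label_rule = c("center", "majority"),
                       accel_unit = "ms2", gyro_unit = "degs",
                       gravity = 9.81) {
  cfg <- list(fs = fs, cutoff_hz = cutoff_hz, filter_order = filter_order,
              rest_s = rest_s, downsample_factor = downsample_factor,
              antialias = antialias, accel_step = accel_step,
              gyro_step = gyro_step, window_s = window_s,
              step_samples = step_samples, fastdtw_radius = fastdtw_radius,
              k_grid = as.integer(k_grid), split_frac = split_frac,
              seed = as.integer(seed), half_window_s = half_window_s,
              smooth_s = smooth_s, min_prominence = min_prominence,
              max_span_s = max_span_s, merge_gap_s = merge_gap_s,
              min_event_s = min_event_s,
              label_rule = match.arg(label_rule),
              accel_unit = accel_unit, gyro_unit = gyro_unit,
              gravity = gravity)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_param("config: ", msg)
  chk(is_scalar_num(cfg$fs) && cfg$fs > 0, "fs must be positive")
  chk(is_scalar_num(cfg$cutoff_hz) && cfg$cutoff_hz > 0 &&
        cfg$cutoff_hz < cfg$fs / 2, "cutoff_hz must lie in (0, fs/2)")
  chk(cfg$filter_order %in% 1:8, "filter_order must be in 1..8")
  chk(is_scalar_num(cfg$rest_s) && cfg$rest_s >= 1, "rest_s must be >= 1 s")
  chk(cfg$downsample_factor >= 1 &&
        cfg$downsample_factor == round(cfg$downsample_factor),
      "downsample_factor must be a positive integer")
  chk(cfg$accel_step > 0 && cfg$gyro_step > 0,
      "quantization steps must be positive")
  chk(cfg$window_s > 0, "window_s must be positive")
  chk(cfg$step_samples >= 1 && cfg$step_samples == round(cfg$step_samples),
      "step_samples must be a positive integer")
  chk(cfg$fastdtw_radius >= 0, "fastdtw_radius must be >= 0")
  chk(length(cfg$k_grid) >= 1 && all(cfg$k_grid >= 1), "k_grid must be >= 1")
  chk(is_scalar_num(cfg$split_frac) && cfg$split_frac > 0 &&
        cfg$split_frac < 1, "split_frac must lie in (0, 1)")
  chk(cfg$merge_gap_s >= 0 && cfg$min_event_s >= 0,
      "merge parameters must be non-negative")
  chk(cfg$half_window_s > 0 && cfg$smooth_s >= 0 && cfg$min_prominence >= 0 &&
        cfg$max_span_s > 0, "labeling parameters out of range")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [run_config()].
#'
#' @param path YAML file path.
#' @return [read_config()] returns a validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop_format("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
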