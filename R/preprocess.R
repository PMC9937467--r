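# Noise filtering, gravity-based vertical alignment, down-sampling and
# quantization of IMU channels.

# Steady-state forward-backward filtering of one channel.  Odd-reflection
# padding plus steady-state initial conditions remove edge transients, so a
# constant channel passes through exactly (unit DC gain).
zero_phase_channel <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  n <- length(x)
  npad <- min(3L * (nfilt - 1L), n - 1L)
  one_pass <- function(z) {
    if (npad > 0) {
      pre <- 2 * z[1] - z[seq(npad + 1, 2)]
      post <- 2 * z[length(z)] - z[seq(length(z) - 1, length(z) - npad)]
      zp <- c(pre, z, post)
    } else zp <- z
    dc <- sum(b) / sum(a)
    y <- signal::filter(b, a, zp,
                        init.x = rep(zp[1], nfilt - 1),
                        init.y = rep(dc * zp[1], nfilt - 1))
    y <- as.numeric(y)
    if (npad > 0) y <- y[(npad + 1):(npad + n)]
    y
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Filters every acceleration and angular-velocity channel with a Butterworth
#' design applied forward and backward.  The default (design order 3, run
#' twice) yields the effective 6th-order zero-delay response conventional in
#' biomechanics; skin-motion artifact above the 30 Hz cut-off is removed
#' while the gesture band is passed with unit DC gain and no phase lag.
#'
#' @param rec an [imu_recording()].
#' @param cutoff_hz cut-off frequency in Hz; must be below the Nyquist rate.
#' @param order Butterworth design order for each pass (effective order is
#'   twice this).
#' @return a filtered [imu_recording()] of identical length and rate.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 30, order = 3) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!is_scalar_num(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2)
    stop_param("cutoff_hz must lie in (0, fs/2) = (0, ", rec$fs / 2, ")")
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "low")
  filt <- function(M) apply(M, 2, function(col)
    zero_phase_channel(bf$b, bf$a, col))
  out <- rec
  out$accel <- filt(rec$accel)
  out$gyro <- filt(rec$gyro)
  dimnames(out$accel) <- dimnames(rec$accel)
  dimnames(out$gyro) <- dimnames(rec$gyro)
  out
}

#' Estimate the gravity direction from a quiet rest window
#'
#' Averages the accelerometer over a rest interval (quiet standing at the
#' start of a subject's first trial) to obtain the gravity direction in the
#' sensor frame.
#'
#' @param rec an [imu_recording()].
#' @param rest_interval `(start_s, end_s)` of the rest window; must lie
#'   inside the recording and span at least 1 s.
#' @return an object of class `gravity_estimate`: `g_dir` (unit 3-vector in
#'   the sensor frame), `g_mag` (mean acceleration norm, m/s^2),
#'   `rest_interval`.
#' @export
estimate_gravity <- function(rec, rest_interval = c(0, 10)) {
  stopifnot(inherits(rec, "imu_recording"))
  if (length(rest_interval) != 2 || diff(rest_interval) < 1)
    stop_param("rest interval must span at least 1 s")
  if (rest_interval[1] < 0 || rest_interval[2] > duration_s(rec) + 1e-9)
    stop_param("rest interval lies outside the recording")
  idx <- which(rec$t >= rest_interval[1] & rec$t <= rest_interval[2])
  v <- colMeans(rec$accel[idx, , drop = FALSE])
  g_mag <- mean(sqrt(rowSums(rec$accel[idx, , drop = FALSE]^2)))
  if (g_mag < 0.5 * 9.81 || g_mag > 1.5 * 9.81)
    ft_stop("implausible rest window: mean |accel| = ",
            signif(g_mag, 4), " m/s^2 (subject was moving?)",
            class = "facetouch_rest_error")
  structure(list(g_dir = v / sqrt(sum(v^2)), g_mag = g_mag,
                 rest_interval = rest_interval),
            class = "gravity_estimate")
}

#' Minimal rotation taking a direction to the vertical axis
#'
#' Rodrigues construction of the geodesic rotation mapping `g_dir` onto
#' (0, 0, 1).  The accelerometer observes only tilt, so heading about the
#' vertical is left arbitrary and the minimal rotation is the natural choice.
#' The anti-parallel case uses a 180-degree rotation about the sensor x axis.
#'
#' @param g_dir unit 3-vector.
#' @return 3 x 3 orthonormal rotation matrix `R` with `R %*% g_dir = c(0,0,1)`.
#' @export
rotation_to_vertical <- function(g_dir) {
  g_dir <- g_dir / sqrt(sum(g_dir^2))
  z <- c(0, 0, 1)
  axis <- cross3(g_dir, z)
  s2 <- sum(axis^2)
  cth <- g_dir[3]
  if (s2 < 1e-24) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 deg about sensor x
  }
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), nrow = 3)  # column-major skew
  diag(3) + K + K %*% K * ((1 - cth) / s2)
}

#' Rotate a recording into the vertically aligned frame
#'
#' Applies the rotation from [rotation_to_vertical()] to every acceleration
#' and angular-velocity sample, so the rest-window gravity maps to
#' (0, 0, g_mag).  This removes the arbitrary mounting orientation of the
#' wrist unit and makes recordings comparable across subjects.
#'
#' @param rec an [imu_recording()].
#' @param g a `gravity_estimate` from [estimate_gravity()].
#' @return the aligned [imu_recording()].
#' @export
vertical_align <- function(rec, g) {
  stopifnot(inherits(rec, "imu_recording"), inherits(g, "gravity_estimate"))
  R <- rotation_to_vertical(g$g_dir)
  out <- rec
  out$accel <- rec$accel %*% t(R)
  out$gyro <- rec$gyro %*% t(R)
  dimnames(out$accel) <- dimnames(rec$accel)
  dimnames(out$gyro) <- dimnames(rec$gyro)
  out
}

#' Decimate a recording to a lower sampling rate
#'
#' Keeps samples at indices 1, 1+factor, 1+2*factor, ...  By default no
#' anti-alias filter is applied before decimation, replicating the published
#' chain (whose 30 Hz-bandwidth signal is decimated to 32 Hz as-is); an
#' optional 12 Hz low-pass can be switched on.
#'
#' @param rec an [imu_recording()].
#' @param factor integer decimation factor; `fs` must be divisible by it.
#' @param antialias logical; pre-filter at `antialias_cutoff` first.
#' @param antialias_cutoff anti-alias cut-off in Hz.
#' @return an [imu_recording()] at `fs / factor`.
#' @export
downsample <- function(rec, factor = 4, antialias = FALSE,
                       antialias_cutoff = 12) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!is_scalar_num(factor) || factor < 1 || factor != round(factor))
    stop_param("factor must be a positive integer")
  if (abs(rec$fs / factor - round(rec$fs / factor)) > 1e-9)
    stop_param("fs = ", rec$fs, " is not divisible by factor = ", factor)
  if (factor == 1 && !antialias) return(rec)
  if (antialias) rec <- lowpass_filter(rec, antialias_cutoff)
  idx <- seq(1L, n_samples(rec), by = factor)
  imu_recording(rec$accel[idx, , drop = FALSE],
                rec$gyro[idx, , drop = FALSE],
                fs = rec$fs / factor, subject_id = rec$subject_id,
                environment = rec$environment)
}

#' Quantize a recording to integer levels
#'
#' `level = round(value / step)` with ties away from zero.  Quantization
#' keeps the DTW local costs integral (no floating-point accumulation in the
#' scores) and shrinks the alphabet the cost matrix is built over.
#'
#' @param rec an [imu_recording()] (normally already at 32 Hz).
#' @param accel_step quantization step for acceleration, m/s^2.
#' @param gyro_step quantization step for angular velocity, deg/s.
#' @return an object of class `quantized_recording` with integer matrices
#'   `accel_q`, `gyro_q`, the sampling rate `fs` and the `steps` used.
#' @export
quantize <- function(rec, accel_step = 0.5, gyro_step = 5) {
  stopifnot(inherits(rec, "imu_recording"))
  if (accel_step <= 0 || gyro_step <= 0)
    stop_param("quantization steps must be positive")
  structure(
    list(subject_id = rec$subject_id, fs = rec$fs,
         accel_q = round_half_away(rec$accel / accel_step),
         gyro_q = round_half_away(rec$gyro / gyro_step),
         steps = c(accel = accel_step, gyro = gyro_step),
         environment = rec$environment),
    class = "quantized_recording")
}

#' Reconstruct a recording from quantized levels
#'
#' @param qrec a `quantized_recording`.
#' @return an [imu_recording()] with `level * step` values (within step/2 of
#'   the pre-quantization signal elementwise).
#' @export
dequantize <- function(qrec) {
  stopifnot(inherits(qrec, "quantized_recording"))
  imu_recording(qrec$accel_q * qrec$steps[["accel"]],
                qrec$gyro_q * qrec$steps[["gyro"]],
                fs = qrec$fs, subject_id = qrec$subject_id,
                environment = qrec$environment)
}

#' Full preprocessing chain
#'
#' Filter, vertically align, decimate and quantize one recording, using a
#' gravity estimate normally taken from the subject's first trial.
#'
#' @param rec an [imu_recording()].
#' @param g a `gravity_estimate`.
#' @param cfg a [run_config()].
#' @return a `quantized_recording` at `fs / downsample_factor`.
#' @export
preprocess_recording <- function(rec, g, cfg = run_config()) {
  rec <- lowpass_filter(rec, cfg$cutoff_hz, cfg$filter_order)
  rec <- vertical_align(rec, g)
  rec <- downsample(rec, cfg$downsample_factor, antialias = cfg$antialias)
  quantize(rec, cfg$accel_step, cfg$gyro_step)
}
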