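test_that("zero-phase filter has exactly unit DC gain", {
  rec <- imu_recording(matrix(c(5, -2, 9.81), 300, 3, byrow = TRUE),
                       matrix(7, 300, 3))
  out <- lowpass_filter(rec)
  expect_equal(max(abs(out$accel[, 1] - 5)), 0, tolerance = 1e-9)
  expect_equal(max(abs(out$accel[, 2] + 2)), 0, tolerance = 1e-9)
  expect_equal(max(abs(out$gyro - 7)), 0, tolerance = 1e-9)
  expect_equal(nrow(out$accel), 300L)
})

test_that("zero-phase filter preserves the symmetry of a symmetric pulse", {
  n <- 513
  t <- seq_len(n)
  pulse <- exp(-(t - 257)^2 / (2 * 8^2))
  rec <- imu_recording(cbind(pulse, 0, 0), matrix(0, n, 3))
  out <- lowpass_filter(rec)$accel[, 1]
  expect_lt(max(abs(out - rev(out))), 1e-9)
})

test_that("stopband attenuation of white noise matches the squared Butterworth response", {
  # oracle: bilinear-transformed order-3 Butterworth magnitude, two passes:
  # |H(f)|^4 with |H(f)|^2 = 1 / (1 + (tan(pi f/fs) / tan(pi fc/fs))^6)
  fs <- 128; fc <- 30
  H4 <- function(f) 1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^6)^2
  x <- withr::with_seed(11, rnorm(2^14))
  rec <- imu_recording(cbind(x, 0, 0), matrix(0, length(x), 3), fs = fs)
  y <- lowpass_filter(rec, fc)$accel[, 1]
  spec_in <- Mod(fft(x))^2
  spec_out <- Mod(fft(y))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  band <- f >= 35 & f <= 64
  measured_db <- 10 * log10(sum(spec_out[band]) / sum(spec_in[band]))
  oracle_db <- 10 * log10(sum(spec_in[band] * H4(f[band])) / sum(spec_in[band]))
  expect_lt(abs(measured_db - oracle_db), 1.5)
  expect_lt(measured_db, -18)
  expect_error(lowpass_filter(rec, 64), "fs/2",
               class = "facetouch_parameter_error")
})

test_that("gravity estimation recovers direction and magnitude", {
  n <- 1281
  rec <- imu_recording(matrix(c(9.81, 0, 0), n, 3, byrow = TRUE),
                       matrix(0, n, 3))
  g <- estimate_gravity(rec, c(0, 10))
  expect_equal(g$g_dir, c(acc_x = 1, acc_y = 0, acc_z = 0))
  expect_equal(g$g_mag, 9.81)

  # noisy rest: averaging 10 s at 128 Hz keeps the direction within 0.5 deg
  errs <- vapply(1:20, function(seed) {
    noisy <- withr::with_seed(seed, imu_recording(
      matrix(c(0, 0, 9.81), n, 3, byrow = TRUE) + matrix(rnorm(3 * n, 0, 0.1), n),
      matrix(0, n, 3)))
    gd <- estimate_gravity(noisy, c(0, 10))$g_dir
    acos(min(1, gd[3])) * 180 / pi
  }, numeric(1))
  expect_lt(mean(errs), 0.5)

  moving <- imu_recording(matrix(30, n, 3), matrix(0, n, 3))
  expect_error(estimate_gravity(moving, c(0, 10)), "implausible",
               class = "facetouch_rest_error")
  expect_error(estimate_gravity(rec, c(0, 0.5)), "at least 1 s",
               class = "facetouch_parameter_error")
})

test_that("vertical alignment is the minimal rotation onto the vertical", {
  n <- 300
  rec <- imu_recording(matrix(c(9.81, 0, 0), n, 3, byrow = TRUE),
                       matrix(c(10, -5, 2), n, 3, byrow = TRUE))
  g <- estimate_gravity(rec, c(0, 2))
  out <- vertical_align(rec, g)
  expect_equal(unname(out$accel[1, ]), c(0, 0, 9.81), tolerance = 1e-9)

  # identity when gravity already vertical
  rec_z <- imu_recording(matrix(c(0, 0, 9.81), n, 3, byrow = TRUE),
                         matrix(1, n, 3))
  expect_equal(vertical_align(rec_z, estimate_gravity(rec_z, c(0, 2))),
               rec_z, tolerance = 1e-12)
})

test_that("rotation_to_vertical is an isometry for random directions", {
  for (seed in 1:50) {
    v <- withr::with_seed(seed, rnorm(3))
    v <- v / sqrt(sum(v^2))
    R <- rotation_to_vertical(v)
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_lt(max(abs(R %*% v - c(0, 0, 1))), 1e-9)
    w <- withr::with_seed(seed + 100, rnorm(3))
    expect_equal(sqrt(sum((R %*% w)^2)), sqrt(sum(w^2)), tolerance = 1e-9)
  }
  # antiparallel case: 180 degrees about x
  R <- rotation_to_vertical(c(0, 0, -1))
  expect_lt(max(abs(R %*% c(0, 0, -1) - c(0, 0, 1))), 1e-12)
  expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-12)
})

test_that("filtering and aligning commute (both linear, rotation static)", {
  rec <- random_recording(n = 600, seed = 8)
  g <- structure(list(g_dir = c(1, 2, 2) / 3, g_mag = 9.81,
                      rest_interval = c(0, 1)), class = "gravity_estimate")
  a <- lowpass_filter(vertical_align(rec, g))
  b <- vertical_align(lowpass_filter(rec), g)
  expect_lt(max(abs(a$accel - b$accel)), 1e-6)
  expect_lt(max(abs(a$gyro - b$gyro)), 1e-6)
})

test_that("downsampling keeps every factor-th sample", {
  rec <- imu_recording(cbind(0:127, 0, 0), matrix(0, 128, 3), fs = 128)
  ds <- downsample(rec, 4)
  expect_equal(nrow(ds$accel), 32L)
  expect_equal(ds$fs, 32)
  expect_equal(unname(ds$accel[, 1]), seq(0, 124, by = 4))
  expect_equal(downsample(ds, 1), ds)
  expect_error(downsample(rec, 2.5), "integer",
               class = "facetouch_parameter_error")
})

test_that("quantization rounds half away from zero and inverts within step/2", {
  rec <- imu_recording(matrix(c(0.26 * 9.81, 0, -2.75), 4, 3, byrow = TRUE),
                       matrix(c(12.5, -12.5, 0), 4, 3, byrow = TRUE), fs = 32)
  q <- quantize(rec, accel_step = 0.5, gyro_step = 5)
  expect_equal(unname(q$accel_q[1, ]), c(5, 0, -6))
  expect_equal(unname(q$gyro_q[1, ]), c(3, -3, 0))
  expect_error(quantize(rec, accel_step = 0), "positive",
               class = "facetouch_parameter_error")

  rnd <- random_recording(n = 200, seed = 4)
  q2 <- quantize(rnd, 0.5, 5)
  back <- dequantize(q2)
  expect_lte(max(abs(back$accel - rnd$accel)), 0.25 + 1e-12)
  expect_lte(max(abs(back$gyro - rnd$gyro)), 2.5 + 1e-12)
})
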