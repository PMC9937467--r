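# Small in-code fixtures shared across test files.

# Recording whose smoothed gyro magnitude has two clean peaks (t = 10 and
# t = 13 s) around a quiet valley at 11.5 s - the double-peak signature of a
# face touch.
double_peak_rec <- function(fs = 32, dur = 20, peaks = c(10, 13), amp = 50) {
  t <- seq(0, dur, by = 1 / fs)
  gx <- amp * exp(-(t - peaks[1])^2 / (2 * 0.3^2)) +
        amp * exp(-(t - peaks[2])^2 / (2 * 0.3^2))
  imu_recording(accel = matrix(rep(c(0, 0, 9.81), each = length(t)),
                               length(t)),
                gyro = cbind(gx, 0, 0), fs = fs)
}

random_recording <- function(n = 100, fs = 128, seed = 1) {
  withr::with_seed(seed, imu_recording(matrix(rnorm(3 * n, 0, 3), n),
                                       matrix(rnorm(3 * n, 0, 40), n),
                                       fs = fs))
}

# A tiny labeled feature matrix with trivially separable classes.
toy_feature_matrix <- function(n_per_class = 20, seed = 3,
                               subject_id = "S01",
                               environment = "controlled") {
  withr::with_seed(seed, {
    centers <- list(`0` = rep(60, 8), `1` = rep(5, 8), `2` = rep(30, 8))
    rows <- lapply(0:2, function(cl) {
      X <- matrix(abs(rep(centers[[cl + 1]], each = n_per_class) +
                        rnorm(8 * n_per_class, 0, 2)), n_per_class)
      cbind(X, cl)
    })
    M <- do.call(rbind, rows)
    df <- data.frame(instant_time = (seq_len(nrow(M)) - 1) * 0.1875,
                     f1 = M[, 1], f2 = M[, 2], f3 = M[, 3], f4 = M[, 4],
                     f5 = M[, 5], f6 = M[, 6], f7 = M[, 7], f8 = M[, 8],
                     label = as.integer(M[, 9]), subject_id = subject_id,
                     environment = environment)
    structure(df, class = c("feature_matrix", "data.frame"))
  })
}
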