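test_that("recording CSV round-trips within 1e-9 relative tolerance", {
  for (n in c(2L, 100L)) {
    rec <- random_recording(n = n)
    path <- withr::local_tempfile(fileext = ".csv")
    write_recording(rec, path)
    back <- read_recording(path, subject_id = rec$subject_id)
    expect_equal(back$accel, rec$accel, tolerance = 1e-9)
    expect_equal(back$gyro, rec$gyro, tolerance = 1e-9)
    expect_equal(back$fs, rec$fs, tolerance = 1e-9)
  }
})

test_that("reader applies unit conversions when declared", {
  rec <- random_recording()
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  g <- read_recording(path, accel_unit = "g", gravity = 9.81)
  expect_equal(g$accel, rec$accel * 9.81, tolerance = 1e-9)
  r <- read_recording(path, gyro_unit = "rads")
  expect_equal(r$gyro, rec$gyro * 180 / pi, tolerance = 1e-9)
})

test_that("reader rejects malformed recordings, naming the offending spot", {
  rec <- random_recording(n = 10)
  path <- withr::local_tempfile(fileext = ".csv")

  write_recording(rec, path)
  df <- read.csv(path)
  df$gyr_y[4] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "gyr_y.*row 4",
               class = "facetouch_format_error")

  df <- read.csv(path); df$gyr_y[4] <- 0
  df$time_s[7] <- df$time_s[7] + 0.01
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "non-uniform",
               class = "facetouch_format_error")

  df <- data.frame(time_s = 0:2 / 128, acc_x = 0, acc_y = 0, acc_z = 0)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "missing column",
               class = "facetouch_format_error")
})

test_that("recording invariants are enforced at construction", {
  expect_error(imu_recording(matrix(0, 1, 3), matrix(0, 1, 3)),
               "at least 2", class = "facetouch_format_error")
  expect_error(imu_recording(matrix(0, 5, 3), matrix(0, 4, 3)),
               "identical length", class = "facetouch_format_error")
  a <- matrix(0, 5, 3); a[3, 2] <- Inf
  expect_error(imu_recording(a, matrix(0, 5, 3)), "row 3",
               class = "facetouch_format_error")
})

test_that("event lists validate, sort and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start_s,end_s,class", "7.25,9.5,2", "1.0,3.5,1"), path)
  ev <- read_events(path)
  expect_s3_class(ev, "event_list")
  expect_equal(ev$start_s, c(1.0, 7.25))   # sorted on read
  expect_equal(ev$class, c(1L, 2L))
  write_events(ev, path)
  expect_equal(read_events(path), ev)

  expect_error(event_list(3, 3, 1), "start_s >= end_s",
               class = "facetouch_format_error")
  expect_error(event_list(c(1, 2), c(3, 4), c(1, 1)), "overlapping",
               class = "facetouch_format_error")
  # different classes may overlap (a touch during another gesture's window)
  expect_silent(event_list(c(1, 2), c(3, 4), c(1, 2)))
})

test_that("log sheets round-trip and reject negative times", {
  log <- log_sheet(c(12.5, 3.25), c("touch", "touch"))
  expect_equal(log$approx_time_s, c(3.25, 12.5))  # sorted
  path <- withr::local_tempfile(fileext = ".csv")
  write_logsheet(log, path)
  expect_equal(read_logsheet(path), log)
  expect_error(log_sheet(-1), "non-negative",
               class = "facetouch_format_error")
})

test_that("run configuration validates and round-trips through YAML", {
  cfg <- run_config(cutoff_hz = 25, accel_step = 0.25, seed = 7L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
  expect_error(run_config(cutoff_hz = 64), "fs/2",
               class = "facetouch_parameter_error")
  expect_error(run_config(split_frac = 1), "split_frac",
               class = "facetouch_parameter_error")
  expect_error(run_config(accel_step = 0), "steps",
               class = "facetouch_parameter_error")
  writeLines("bogus_key: 3", path)
  expect_error(read_config(path), "unknown config key",
               class = "facetouch_format_error")
})
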