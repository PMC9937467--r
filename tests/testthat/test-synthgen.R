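test_that("noiseless face touches show the double-peak / quiet-dwell signature", {
  gp0 <- gesture_params(accel_noise_sd = 0, gyro_noise_sd = 0)
  for (seed in 1:30) {
    g <- simulate_gesture("face_touch", gp0, seed = seed)
    mag <- sqrt(rowSums(g$gyro^2))
    pk <- facetouch:::find_peaks(mag, min_prominence = 20)
    expect_length(pk, 2L)
    expect_true(all(mag[pk] > 20))
    expect_lt(min(mag[pk[1]:pk[2]]), 5)
  }
})

test_that("the signature survives default sensor noise in >= 95% of gestures", {
  gp <- gesture_params()
  ok <- 0L
  for (seed in 1:100) {
    g <- simulate_gesture("face_touch", gp, seed = seed)
    mag <- sqrt(rowSums(g$gyro^2))
    sm <- facetouch:::moving_average(mag, 16L)
    pk <- facetouch:::find_peaks(sm, min_prominence = 20)
    if (length(pk) == 2 && min(sm[pk[1]:pk[2]]) < 10) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("rest segments are gravity plus noise", {
  r <- simulate_gesture("rest", gesture_params(), duration_s = 10, seed = 2)
  expect_equal(mean(sqrt(rowSums(r$accel^2))), 9.81, tolerance = 0.05)
  expect_lt(max(abs(r$gyro)), 3 * 1 * sqrt(3) * 2)
  expect_equal(r$label, 0L)
})

test_that("gesture synthesis is bit-identical under a fixed seed", {
  a <- simulate_gesture("scratch_head", seed = 12)
  b <- simulate_gesture("scratch_head", seed = 12)
  expect_identical(a, b)
  c <- simulate_gesture("scratch_head", seed = 13)
  expect_false(identical(a$gyro, c$gyro))
  expect_error(simulate_gesture("jumping"), "unknown class",
               class = "facetouch_parameter_error")
})

test_that("sessions honour their schedule and log every face touch", {
  s <- simulate_session("S05", "natural", n_face = 5, duration_s = 1200,
                        seed = 44)
  expect_equal(sum(s$truth$class == 1L), 5L)
  expect_equal(nrow(s$logsheet), 5L)
  expect_equal(facetouch:::duration_s(s$recording), 1200, tolerance = 1)
  # 10 s of rest on both ends
  expect_gte(min(s$truth$start_s), 10)
  expect_lte(max(s$truth$end_s), 1190 + 1)
  # each log entry within jitter of a true touch midpoint
  mids <- (s$truth$start_s + s$truth$end_s)[s$truth$class == 1L] / 2
  expect_true(all(vapply(s$logsheet$approx_time_s,
                         function(a) min(abs(a - mids)) <= 2 + 1e-9,
                         logical(1))))

  pure <- simulate_session("S06", "natural", n_face = 0,
                           confounders_per_class = c(eating = 0),
                           duration_s = 60, seed = 4)
  expect_equal(nrow(pure$truth), 0L)
  expect_lt(max(abs(pure$recording$gyro)), 10)

  expect_error(simulate_session("S07", "natural", n_face = 40,
                                duration_s = 60, seed = 1),
               "infeasible", class = "facetouch_parameter_error")
})

test_that("sessions with different seeds place events differently", {
  a <- simulate_session("S01", "controlled", n_face = 3,
                        confounders_per_class = c(eating = 1), seed = 5)
  b <- simulate_session("S01", "controlled", n_face = 3,
                        confounders_per_class = c(eating = 1), seed = 6)
  expect_false(identical(a$truth$start_s, b$truth$start_s))
})

test_that("cohorts are reproducible with per-subject individuality", {
  co <- simulate_cohort(n_subjects = 2, seed = 31, controlled_reps = 2,
                        natural_n_face = 2, natural_conf_each = 1,
                        natural_duration_s = 120)
  expect_length(co$sessions, 4L)
  expect_equal(vapply(co$sessions, `[[`, character(1), "environment"),
               rep(c("controlled", "natural"), 2))
  expect_equal(unique(vapply(co$sessions, `[[`, character(1), "subject_id")),
               c("S01", "S02"))
  p <- co$profiles
  expect_false(isTRUE(all.equal(p$S01$dur_scale, p$S02$dur_scale)) &&
                 isTRUE(all.equal(p$S01$g_rest, p$S02$g_rest)))
  co2 <- simulate_cohort(n_subjects = 2, seed = 31, controlled_reps = 2,
                         natural_n_face = 2, natural_conf_each = 1,
                         natural_duration_s = 120)
  expect_identical(co$sessions[[1]]$recording, co2$sessions[[1]]$recording)
  expect_identical(co$sessions[[4]]$truth, co2$sessions[[4]]$truth)
})

test_that("cohorts write to disk with a complete manifest", {
  co <- simulate_cohort(n_subjects = 1, seed = 8, controlled_reps = 1,
                        natural_n_face = 1, natural_conf_each = 0,
                        natural_duration_s = 60)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_equal(nrow(man), 2L)
  expect_true(all(file.exists(file.path(dir, man$recording))))
  back <- read_recording(file.path(dir, man$recording[1]))
  expect_equal(nrow(back$accel), nrow(co$sessions[[1]]$recording$accel))
  ev <- read_events(file.path(dir, man$events[2]))
  expect_equal(ev$class, co$sessions[[2]]$truth$class)
})
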