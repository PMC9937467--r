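# Turning approximate self-reported touch instants and scripted schedules
# into event boundaries and per-sample class labels.
#
# Classes: 0 = other, 1 = face touch, 2 = confounding gesture.

#' Per-sample label vector
#'
#' @param labels integer vector with values in \{0, 1, 2\}.
#' @param fs sampling rate the labels refer to, Hz.
#' @return an integer vector of class `label_vector` with attribute `fs`.
#' @export
label_vector <- function(labels, fs) {
  labels <- as.integer(labels)
  if (!all(labels %in% 0:2)) stop_format("labels must lie in {0,1,2}")
  structure(labels, fs = fs, class = "label_vector")
}

# mean over a centred window, shrinking at the edges
moving_average <- function(x, half) {
  if (half < 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Local maxima with topographic prominence.  A peak is a sample strictly
# above its left neighbour and not below its right neighbour; prominence is
# the drop to the higher of the two key saddles.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1 && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    if (j < 1) lbase <- lmin else lbase <- lmin
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    rbase <- rmin
    h - max(lbase, rbase)
  }, numeric(1))
  cand[prom >= min_prominence]
}

#' Refine a logged face-touch instant into event boundaries
#'
#' A face touch shows a characteristic double peak in the resultant angular
#' velocity (reach lobe, quiet dwell at the face, return lobe).  The smoothed
#' gyroscope magnitude is searched within `half_window` of the logged
#' instant; among prominent local maxima, the pair of consecutive peaks
#' spanning at most `max_span_s` that lies nearest the logged instant is
#' taken as the start/end of the touch, with the dwell valley in between.
#' (Restricting to close peak pairs keeps quiet rest gaps on either side of
#' the gesture from masquerading as the dwell.)
#'
#' @param rec an [imu_recording()].
#' @param approx_t logged approximate touch instant, s.
#' @param half_window search half-window around `approx_t`, s.
#' @param smooth_s moving-average smoothing span for the magnitude, s.
#' @param min_prominence minimum peak prominence, deg/s.
#' @param max_span_s maximum start-to-end peak spacing considered one touch, s.
#' @return numeric `(start_s, end_s)` with attribute `valley_s`, the time of
#'   the dwell minimum (`start_s < valley_s < end_s`).
#' @export
refine_touch_event <- function(rec, approx_t, half_window = 5,
                               smooth_s = 0.25, min_prominence = 10,
                               max_span_s = 3) {
  stopifnot(inherits(rec, "imu_recording"))
  if (approx_t < 0 || approx_t > duration_s(rec))
    stop_label("logged instant ", approx_t, " s lies outside the recording")
  mag <- sqrt(rowSums(rec$gyro^2))
  sm <- moving_average(mag, round(smooth_s * rec$fs / 2))
  win <- which(rec$t >= approx_t - half_window & rec$t <= approx_t + half_window)
  # peaks (and their prominences) are assessed within the search window
  pk <- find_peaks(sm[win], min_prominence) + win[1] - 1L
  if (length(pk) < 2)
    stop_label("no qualifying angular-velocity maxima near t = ", approx_t,
               " s; flagged for manual review")
  spans <- rec$t[pk[-1]] - rec$t[pk[-length(pk)]]
  ok <- which(spans <= max_span_s)
  if (!length(ok))
    stop_label("no peak pair within ", max_span_s, " s near t = ", approx_t,
               " s; flagged for manual review")
  t1 <- rec$t[pk[ok]]
  t2 <- rec$t[pk[ok + 1]]
  dist <- pmax(0, pmax(t1 - approx_t, approx_t - t2))
  best <- order(dist, abs((t1 + t2) / 2 - approx_t))[1]
  i1 <- pk[ok[best]]
  i2 <- pk[ok[best] + 1]
  interior <- (i1 + 1):(i2 - 1)
  valley <- interior[which.min(sm[interior])]
  structure(c(start_s = rec$t[i1], end_s = rec$t[i2]),
            valley_s = rec$t[valley])
}

#' Label a natural-environment trial from its log sheet
#'
#' Refines every logged instant with [refine_touch_event()] and builds the
#' face-touch event list plus the per-sample label vector (1 inside refined
#' touches, 0 elsewhere; confounding gestures are not logged in natural
#' trials and remain 0).
#'
#' @param rec an [imu_recording()].
#' @param log a [log_sheet()].
#' @param half_window,smooth_s,min_prominence,max_span_s see
#'   [refine_touch_event()].
#' @param on_error `"stop"` raises a labeling error on the first entry that
#'   cannot be refined (or on colliding refinements); `"skip"` drops such
#'   entries and lists their indices in the events' `failed_entries`
#'   attribute, the review report of the labeling stage.
#' @return `list(events, labels)`: an [event_list()] and a [label_vector()]
#'   at the recording's rate.
#' @export
label_from_logsheet <- function(rec, log, half_window = 5, smooth_s = 0.25,
                                min_prominence = 10, max_span_s = 3,
                                on_error = c("stop", "skip")) {
  stopifnot(inherits(rec, "imu_recording"), inherits(log, "log_sheet"))
  on_error <- match.arg(on_error)
  empty <- function(failed) {
    ev <- event_list()
    attr(ev, "failed_entries") <- failed
    list(events = ev,
         labels = label_vector(integer(n_samples(rec)), rec$fs))
  }
  if (nrow(log) == 0) return(empty(integer()))
  failed <- integer()
  start <- end <- rep(NA_real_, nrow(log))
  for (i in seq_len(nrow(log))) {
    b <- tryCatch(
      refine_touch_event(rec, log$approx_time_s[i], half_window, smooth_s,
                         min_prominence, max_span_s),
      facetouch_label_error = function(e) {
        if (on_error == "stop") stop(e)
        NULL
      })
    if (is.null(b)) failed <- c(failed, i) else { start[i] <- b[1]; end[i] <- b[2] }
  }
  ok <- which(!is.na(start))
  if (!length(ok)) return(empty(failed))
  # distinct entries refined to identical or overlapping events collide
  o <- ok[order(start[ok])]
  keep <- o[1]
  for (i in o[-1]) {
    prev <- keep[length(keep)]
    if (start[i] < end[prev] || start[i] == start[prev]) {
      if (on_error == "stop")
        stop_label("refined events for log entries ", prev, " and ", i,
                   " overlap; review the log sheet")
      failed <- c(failed, i)
    } else keep <- c(keep, i)
  }
  events <- event_list(start[keep], end[keep], rep(1L, length(keep)))
  attr(events, "failed_entries") <- sort(failed)
  list(events = events,
       labels = labels_from_events(events, n_samples(rec), rec$fs))
}

#' Per-sample labels from an event schedule
#'
#' Samples inside face-touch events get 1, inside confounding events 2, all
#' others 0.  Isolated events are closed intervals; where two events share a
#' boundary sample the earlier event keeps it (closed-open at joins).
#'
#' @param events an [event_list()].
#' @param n number of samples to label.
#' @param fs sampling rate, Hz.
#' @return a [label_vector()].
#' @export
labels_from_events <- function(events, n, fs) {
  stopifnot(inherits(events, "event_list"))
  lab <- integer(n)
  t <- seq(0, by = 1 / fs, length.out = n)
  for (i in seq_len(nrow(events))) {
    idx <- which(t >= events$start_s[i] - 1e-9 & t <= events$end_s[i] + 1e-9)
    idx <- idx[lab[idx] == 0L]
    lab[idx] <- events$class[i]
  }
  label_vector(lab, fs)
}

#' Label a controlled (scripted) trial
#'
#' Controlled trials follow a known schedule of face touches and confounding
#' gestures, so labels come straight from the script.
#'
#' @param rec an [imu_recording()].
#' @param schedule an [event_list()] of scripted gestures; must lie inside
#'   the recording and contain no overlapping entries (of any class).
#' @return a [label_vector()] at the recording's rate.
#' @export
label_controlled_trial <- function(rec, schedule) {
  stopifnot(inherits(rec, "imu_recording"), inherits(schedule, "event_list"))
  if (nrow(schedule)) {
    if (min(schedule$start_s) < 0 || max(schedule$end_s) > duration_s(rec) + 1e-9)
      stop_label("schedule extends beyond the recording")
    if (nrow(schedule) > 1 &&
        any(schedule$start_s[-1] < schedule$end_s[-nrow(schedule)]))
      stop_label("overlapping schedule entries")
  }
  labels_from_events(schedule, n_samples(rec), rec$fs)
}
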