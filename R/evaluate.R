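# Event-level matching of predictions to ground truth and the detection
# metrics (sensitivity, precision, accuracy, FPR, FDR).
#
# The unit of analysis is the event, not the sample: a predicted face-touch
# period that overlaps a true touch by any positive amount counts as a
# correct detection, matching how an on-wrist monitor would be judged
# (number of touches and approximate time, not exact extent).

#' Event-level confusion counts
#'
#' `RP` = condition-positive events (true face touches exposed to scoring);
#' `RN` = condition-negative events (confounding gestures, plus rest
#' segments when scored); `TP`/`FN` partition `RP`; `FP` counts predicted
#' events overlapping no true touch; `TN` counts negatives left untouched by
#' predictions.
#'
#' @param RP,RN,TP,TN,FP,FN non-negative integers with `TP + FN == RP`,
#'   `TN <= RN`.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(RP, RN, TP, TN, FP, FN) {
  v <- c(RP = RP, RN = RN, TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    stop_param("counts must be non-negative integers")
  if (TP + FN != RP) stop_param("TP + FN must equal RP")
  if (TN > RN) stop_param("TN cannot exceed RN")
  structure(as.list(as.integer(v)), names = names(v),
            class = "confusion_counts")
}

#' Merge predicted-positive instants into predicted events
#'
#' Consecutive positive instants whose start times differ by at most
#' `merge_gap_s` are grouped; each group spans from its first window start
#' to its last window start plus `window_s`.  Because every window is
#' `window_s` long, groups whose extents still overlap are unioned (a
#' predicted period cannot overlap itself), and events shorter than
#' `min_event_s` are dropped.
#'
#' @param instant_times window start times, s (ascending).
#' @param positive logical vector: was the instant predicted as face touch?
#' @param window_s window length, s.
#' @param merge_gap_s largest instant gap bridged within one event, s.
#' @param min_event_s minimum retained event duration, s.
#' @return an [event_list()] of predicted face touches.
#' @export
instants_to_events <- function(instant_times, positive, window_s = 3,
                               merge_gap_s = 0.4, min_event_s = 0.5) {
  stopifnot(length(instant_times) == length(positive))
  tt <- instant_times[as.logical(positive)]
  if (!length(tt)) return(event_list())
  if (is.unsorted(tt)) tt <- sort(tt)
  new_grp <- c(TRUE, diff(tt) > merge_gap_s + 1e-9)
  grp <- cumsum(new_grp)
  start <- tapply(tt, grp, min)
  end <- tapply(tt, grp, max) + window_s
  # union extents that still overlap
  o <- order(start)
  start <- start[o]; end <- end[o]
  keep_s <- start[1]; keep_e <- end[1]
  us <- numeric(); ue <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= keep_e) keep_e <- max(keep_e, end[i])
    else { us <- c(us, keep_s); ue <- c(ue, keep_e)
           keep_s <- start[i]; keep_e <- end[i] }
  }
  us <- c(us, keep_s); ue <- c(ue, keep_e)
  long <- (ue - us) >= min_event_s
  event_list(us[long], ue[long], rep(1L, sum(long)))
}

overlaps_any <- function(s, e, starts, ends) {
  if (!length(starts)) return(logical(length(s)))
  vapply(seq_along(s), function(i)
    any(pmin(e[i], ends) - pmax(s[i], starts) > 0), logical(1))
}

#' Match predicted events to ground truth
#'
#' A true face touch overlapped by at least one predicted event (any
#' positive-length intersection) is a TP; each true event counts once
#' however many predictions cover it.  A predicted event overlapping no true
#' touch is an FP.  A scored negative event overlapped by no prediction is a
#' TN.  TP counts true events while FP counts predicted events - the
#' asymmetry is deliberate.
#'
#' @param pred predicted [event_list()] (face touches).
#' @param truth ground-truth face-touch [event_list()].
#' @param scored_negatives [event_list()] of negative events exposed to
#'   scoring (confounding gestures, optionally rest segments); may be empty.
#' @return a [confusion_counts()].
#' @export
match_events <- function(pred, truth, scored_negatives = NULL) {
  stopifnot(inherits(pred, "event_list"), inherits(truth, "event_list"))
  neg <- scored_negatives %||% event_list()
  tp_hit <- overlaps_any(truth$start_s, truth$end_s, pred$start_s, pred$end_s)
  fp_hit <- !overlaps_any(pred$start_s, pred$end_s, truth$start_s, truth$end_s)
  tn_hit <- !overlaps_any(neg$start_s, neg$end_s, pred$start_s, pred$end_s)
  confusion_counts(RP = nrow(truth), RN = nrow(neg),
                   TP = sum(tp_hit), TN = sum(tn_hit),
                   FP = sum(fp_hit), FN = sum(!tp_hit))
}

#' Detection metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN); precision = TP/(TP+FP); FPR = FP/(FP+TN);
#' FDR = FP/(FP+TP); accuracy = (TP+TN)/(RP+RN), which reduces to TP/RP when
#' no negatives are scored (natural-environment trials).  All reported as
#' integer percent, ties rounded up; a zero denominator yields `NA` (the
#' metric is undefined, never 0).
#'
#' @param cc a [confusion_counts()].
#' @return a named list of class `detection_metrics` with elements
#'   `sensitivity`, `precision`, `accuracy`, `fpr`, `fdr`, each an integer
#'   percent between 0 and 100, or NA.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  pct <- function(num, den) if (den == 0) NA_real_ else
    round_half_up(100 * num / den)
  structure(list(
    sensitivity = pct(cc$TP, cc$TP + cc$FN),
    precision = pct(cc$TP, cc$TP + cc$FP),
    accuracy = pct(cc$TP + cc$TN, cc$RP + cc$RN),
    fpr = pct(cc$FP, cc$FP + cc$TN),
    fdr = pct(cc$FP, cc$FP + cc$TP)),
    class = "detection_metrics")
}

#' Per-k metrics table
#'
#' One row per k with counts and metrics.  In natural mode the TN, FPR and
#' FDR columns are omitted: when only face touches are labeled there are no
#' scored negatives to count.
#'
#' @param counts_by_k named list (names = k) of [confusion_counts()].
#' @param mode `"controlled"` or `"natural"`.
#' @return a `data.frame`, one row per k.
#' @export
report_table <- function(counts_by_k, mode = c("controlled", "natural")) {
  mode <- match.arg(mode)
  if (!length(counts_by_k)) stop_param("need at least one k")
  rows <- lapply(names(counts_by_k), function(kname) {
    cc <- counts_by_k[[kname]]
    m <- compute_metrics(cc)
    data.frame(K = as.integer(kname), RP = cc$RP, TP = cc$TP, FP = cc$FP,
               TN = cc$TN, FN = cc$FN,
               sensitivity = m$sensitivity, precision = m$precision,
               accuracy = m$accuracy, fpr = m$fpr, fdr = m$fdr)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$K), ]
  rownames(out) <- NULL
  if (mode == "natural")
    out <- out[, setdiff(names(out), c("TN", "fpr", "fdr"))]
  out
}

#' Published benchmark confusion counts
#'
#' Event-level confusion counts and printed integer-percent metrics from a
#' published wrist-IMU face-touch detection benchmark (10 values of k in
#' 3..21, controlled and natural environments), bundled as a plain-text
#' fixture.  `RN` for the controlled environment is inferred from the
#' printed accuracies (it was not printed); the natural environment scored
#' no negatives (`RN = 0`, accuracy = sensitivity).
#'
#' @return a `data.frame` with columns `environment`, `k`, `RP`, `RN`, `TP`,
#'   `FP`, `TN`, `FN` and printed `sensitivity`, `precision`, `accuracy`,
#'   `fpr`, `fdr` (NA where not printed).
#' @export
load_benchmark_counts <- function() {
  path <- system.file("extdata", "published_benchmark_counts.csv",
                      package = "facetouch", mustWork = TRUE)
  utils::read.csv(path)
}

#' Recompute metrics from benchmark counts and compare to printed values
#'
#' Feeds each row's counts through [compute_metrics()] and checks the
#' printed integer percentages.  Controlled-environment accuracy is checked
#' against the inferred `RN`; FPR/FDR are skipped where the benchmark did
#' not report them.
#'
#' @param counts a `data.frame` as returned by [load_benchmark_counts()].
#' @return the input with recomputed metric columns (`*_rc`) and a logical
#'   `all_match` column.
#' @export
verify_metric_table <- function(counts = load_benchmark_counts()) {
  rc <- t(vapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    cc <- confusion_counts(RP = r$RP, RN = r$RN, TP = r$TP, TN = r$TN,
                           FP = r$FP, FN = r$FN)
    unlist(compute_metrics(cc))
  }, numeric(5)))
  colnames(rc) <- paste0(colnames(rc), "_rc")
  out <- cbind(counts, rc)
  same <- function(a, b) is.na(a) | (!is.na(b) & a == b)
  out$all_match <- same(out$sensitivity, out$sensitivity_rc) &
    same(out$precision, out$precision_rc) &
    same(out$accuracy, out$accuracy_rc) &
    same(out$fpr, out$fpr_rc) & same(out$fdr, out$fdr_rc)
  out
}
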