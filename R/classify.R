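# KNN majority-vote classification: randomized 70/30 instant split, k-grid
# sweep and leave-one-subject-out cross-validation.

#' Randomized train/test split of instants
#'
#' Instants are shuffled with a seeded generator; the first
#' `round(frac * n)` (half-up) form the training set.  Controlled and
#' natural datasets are split independently by the pipeline (one call per
#' environment).
#'
#' @param fm a labeled `feature_matrix`.
#' @param frac training fraction, strictly inside (0, 1).
#' @param seed RNG seed; the same seed reproduces the same partition.
#' @return `list(train, test, train_idx, test_idx)`.
#' @export
split_train_test <- function(fm, frac = 0.7, seed = 42L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is_scalar_num(frac) || frac <= 0 || frac >= 1)
    stop_param("frac must lie strictly inside (0, 1)")
  n <- nrow(fm)
  if (n < 10) stop_param("need at least 10 instants to split")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- round_half_up(frac * n)
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[(n_train + 1):n])
  list(train = fm[train_idx, , drop = FALSE],
       test = fm[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Fit (store) a KNN model
#'
#' KNN is non-parametric: fitting stores the training instants and labels.
#' No feature standardization is applied; all eight features live on the
#' same DTW-score scale.
#'
#' @param X m x 8 numeric matrix of training features.
#' @param y integer labels in \{0, 1, 2\}.
#' @param k number of neighbours (1 <= k <= m).
#' @return an object of class `knn_model`.
#' @export
knn_fit <- function(X, y, k = 3L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop_param("X and y disagree in length")
  if (!all(y %in% 0:2)) stop_param("labels must lie in {0,1,2}")
  if (k < 1 || k > nrow(X)) stop_param("k must lie in [1, m]")
  structure(list(train_X = X, train_y = y, k = as.integer(k)),
            class = "knn_model")
}

#' Predict with a KNN model
#'
#' Euclidean distance in the 8-D feature space; the k nearest training
#' instants vote and the plurality class wins.  Ties are broken by the
#' smaller summed distance among tied classes, then by the class of the
#' single nearest neighbour, so predictions are deterministic.
#'
#' @param model a [knn_fit()] result.
#' @param Q q x 8 numeric matrix of query features.
#' @return integer vector of q predicted labels.
#' @export
knn_predict <- function(model, Q) {
  stopifnot(inherits(model, "knn_model"))
  Q <- as.matrix(Q)
  if (ncol(Q) != ncol(model$train_X)) stop_param("query dimension mismatch")
  if (nrow(Q) == 0) return(integer())
  drop(knn_sweep_cpp(model$train_X, model$train_y, Q, model$k))
}

fm_matrix <- function(fm) as.matrix(fm[, feature_cols, drop = FALSE])

#' Sweep the k grid over one train/test split
#'
#' @param train,test labeled `feature_matrix` objects.
#' @param k_grid neighbour counts (odd 3..21 by default).
#' @return integer matrix, one column of test predictions per k
#'   (`colnames` `"k3"`, `"k5"`, ...).
#' @export
sweep_k <- function(train, test, k_grid = seq(3L, 21L, by = 2L)) {
  k_grid <- as.integer(k_grid)
  if (nrow(test) == 0) {
    out <- matrix(integer(), nrow = 0, ncol = length(k_grid))
    colnames(out) <- paste0("k", k_grid)
    return(out)
  }
  preds <- knn_sweep_cpp(fm_matrix(train), as.integer(train$label),
                         fm_matrix(test), k_grid)
  colnames(preds) <- paste0("k", k_grid)
  preds
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains on all other subjects' instants of the same
#' environment and evaluates event-level detection on the held-out subject,
#' for every k in the grid.  Reported are per-fold metrics, their average
#' over folds per k, and the grand average over the k grid.
#'
#' @param sessions list of session records as produced by
#'   [extract_session_features()]: each holds a labeled `feature_matrix`
#'   (`fm`), the ground-truth `event_list` (`truth`), `subject_id` and
#'   `environment`.
#' @param k_grid neighbour counts to sweep.
#' @param window_s sliding-window length (s), for predicted-event extents.
#' @param merge_gap_s,min_event_s see [instants_to_events()].
#' @return `list(per_fold, per_k, average)`: per-fold per-k metric rows, the
#'   fold-averaged table per k, and the grand-average row per environment.
#' @export
loso_cv <- function(sessions, k_grid = seq(3L, 21L, by = 2L), window_s = 3,
                    merge_gap_s = 0.4, min_event_s = 0.5) {
  k_grid <- as.integer(k_grid)
  subjects <- unique(vapply(sessions, `[[`, character(1), "subject_id"))
  if (length(subjects) < 2) stop_param("LOSO needs at least 2 subjects")
  envs <- unique(vapply(sessions, `[[`, character(1), "environment"))
  rows <- list()
  for (env in envs) {
    env_sessions <- Filter(function(s) s$environment == env, sessions)
    fm_all <- do.call(rbind, lapply(env_sessions, `[[`, "fm"))
    for (subj in subjects) {
      held <- Filter(function(s) s$subject_id == subj, env_sessions)
      if (!length(held)) next
      if (sum(vapply(held, function(s) nrow(s$fm), integer(1))) == 0)
        stop_param("subject ", subj, " has no instants")
      train <- fm_all[fm_all$subject_id != subj, , drop = FALSE]
      for (s in held) {
        preds <- sweep_k(train, s$fm, k_grid)
        for (ki in seq_along(k_grid)) {
          pred_ev <- instants_to_events(
            s$fm$instant_time, preds[, ki] == 1L, window_s = window_s,
            merge_gap_s = merge_gap_s, min_event_s = min_event_s)
          truth_face <- s$truth[s$truth$class == 1L, , drop = FALSE]
          negatives <- s$truth[s$truth$class == 2L, , drop = FALSE]
          cc <- match_events(pred_ev, truth_face, negatives)
          rows[[length(rows) + 1L]] <-
            data.frame(environment = env, subject = subj, k = k_grid[ki],
                       as.data.frame(unclass(cc)[c("RP", "RN", "TP", "TN",
                                                   "FP", "FN")]))
        }
      }
    }
  }
  per_session <- do.call(rbind, rows)
  # one fold = one held-out subject: pool counts over that subject's sessions
  agg <- stats::aggregate(
    per_session[, c("RP", "RN", "TP", "TN", "FP", "FN")],
    by = per_session[, c("environment", "subject", "k")], FUN = sum)
  met <- t(vapply(seq_len(nrow(agg)), function(i) {
    m <- compute_metrics(do.call(confusion_counts, as.list(agg[i, c(
      "RP", "RN", "TP", "TN", "FP", "FN")])))
    unlist(m)
  }, numeric(5)))
  per_fold <- cbind(agg, met)
  per_k <- stats::aggregate(
    per_fold[, c("sensitivity", "precision", "accuracy", "fpr", "fdr")],
    by = per_fold[, c("environment", "k")],
    FUN = function(x) mean(x, na.rm = TRUE))
  per_k <- per_k[order(per_k$environment, per_k$k), ]
  rownames(per_k) <- NULL
  average <- stats::aggregate(
    per_k[, c("sensitivity", "precision", "accuracy", "fpr", "fdr")],
    by = per_k[, "environment", drop = FALSE],
    FUN = function(x) mean(x, na.rm = TRUE))
  list(per_fold = per_fold, per_k = per_k, average = average)
}
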