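fm_matrix_for_test <- function(fm)
  as.matrix(fm[, paste0("f", 1:8), drop = FALSE])

make_session <- function(subject, environment = "controlled", seed = 1) {
  fm <- toy_feature_matrix(n_per_class = 30, seed = seed,
                           subject_id = subject, environment = environment)
  fm <- fm[order(fm$instant_time), ]
  # truth: one face-touch event covering the label-1 instants, one confounder
  t1 <- range(fm$instant_time[fm$label == 1L])
  t2 <- range(fm$instant_time[fm$label == 2L])
  truth <- event_list(c(t1[1], t2[1]), c(t1[2] + 3, t2[2] + 3), c(1L, 2L))
  list(subject_id = subject, environment = environment, fm = fm,
       truth = truth)
}

test_that("the 70/30 split is a seeded disjoint cover with the right sizes", {
  fm <- toy_feature_matrix(n_per_class = 10)  # n = 30
  sp <- split_train_test(fm, frac = 0.7, seed = 5)
  expect_equal(nrow(sp$train), 21L)
  expect_equal(nrow(sp$test), 9L)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(30))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)

  sp2 <- split_train_test(fm, frac = 0.7, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_train_test(fm, frac = 0.7, seed = 6)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  small <- fm[1:10, ]
  sp4 <- split_train_test(small, frac = 0.7, seed = 1)
  expect_equal(nrow(sp4$train), 7L)
  expect_error(split_train_test(fm, frac = 1), "strictly",
               class = "facetouch_parameter_error")
  expect_error(split_train_test(fm[1:9, ], frac = 0.7), "at least 10",
               class = "facetouch_parameter_error")
})

test_that("KNN votes by plurality with the documented tie-breaks", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5))
  X8 <- cbind(X, matrix(0, 4, 6))
  y <- c(1L, 1L, 2L, 0L)
  m1 <- knn_fit(X8, y, k = 1)
  expect_equal(knn_predict(m1, X8[4, , drop = FALSE]), 0L)
  m3 <- knn_fit(X8, y, k = 3)
  expect_equal(knn_predict(m3, matrix(0, 1, 8)), 1L)  # neighbours (1,1,2)

  # 2-2 count tie resolved by smaller summed distance
  X2 <- cbind(c(1, 2, 3, 4), matrix(0, 4, 7))
  y2 <- c(1L, 2L, 2L, 1L)
  m4 <- knn_fit(X2, y2, k = 4)
  expect_equal(knn_predict(m4, matrix(c(2.4, rep(0, 7)), 1)), 2L)
  expect_error(knn_fit(X8, y, k = 9), class = "facetouch_parameter_error")
})

test_that("KNN agrees with the brute-force all-pairs oracle", {
  dat <- withr::with_seed(17, {
    X <- matrix(runif(300 * 8, 0, 50), 300)
    y <- sample(0:2, 300, TRUE)
    Q <- matrix(runif(200 * 8, 0, 50), 200)
    list(X = X, y = y, Q = Q)
  })
  for (k in c(1L, 3L, 7L, 15L)) {
    got <- knn_predict(knn_fit(dat$X, dat$y, k), dat$Q)
    want <- as.integer(knn_brute(dat$X, dat$y, dat$Q, k))
    expect_identical(got, want)
  }
})

test_that("the k sweep matches individual predictions and handles empties", {
  fm <- toy_feature_matrix(n_per_class = 15)
  sp <- split_train_test(fm, seed = 2)
  preds <- sweep_k(sp$train, sp$test, k_grid = c(3L, 5L))
  expect_equal(dim(preds), c(nrow(sp$test), 2L))
  expect_equal(colnames(preds), c("k3", "k5"))
  direct <- knn_predict(knn_fit(fm_matrix_for_test(sp$train),
                                sp$train$label, 3), fm_matrix_for_test(sp$test))
  expect_identical(unname(preds[, "k3"]), direct)
  empty <- sweep_k(sp$train, sp$test[0, ], k_grid = c(3L, 5L))
  expect_equal(dim(empty), c(0L, 2L))
})

test_that("LOSO folds never share a subject and identical subjects give equal folds", {
  sessions <- lapply(c("A", "B", "C"), make_session, seed = 9)
  res <- loso_cv(sessions, k_grid = c(3L, 5L))
  expect_equal(sort(unique(res$per_fold$subject)), c("A", "B", "C"))
  expect_equal(nrow(res$per_fold), 3L * 2L)
  # subjects are exact copies, so every fold sees the same problem
  for (k in c(3L, 5L)) {
    rows <- res$per_fold[res$per_fold$k == k, ]
    expect_equal(length(unique(rows$sensitivity)), 1L)
    expect_equal(length(unique(rows$TP)), 1L)
  }
  expect_error(loso_cv(sessions[1], k_grid = 3L), "2 subjects",
               class = "facetouch_parameter_error")
})

test_that("LOSO is deterministic given the data", {
  sessions <- lapply(c("A", "B"), function(s) make_session(s, seed = match(s, c("A", "B"))))
  r1 <- loso_cv(sessions, k_grid = 3L)
  r2 <- loso_cv(sessions, k_grid = 3L)
  expect_identical(r1, r2)
})
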