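# Independent oracles, deliberately naive: exhaustive path enumeration for
# DTW (tiny series only) and brute-force all-pairs KNN with the documented
# tie-break chain.

dtw_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, cost) {
    cost <- cost + abs(a[i] - b[j])
    if (cost >= best) return(invisible())
    if (i == n && j == m) { best <<- cost; return(invisible()) }
    if (i < n && j < m) walk(i + 1, j + 1, cost)
    if (i < n) walk(i + 1, j, cost)
    if (j < m) walk(i, j + 1, cost)
  }
  walk(1, 1, 0)
  best
}

knn_brute <- function(X, y, Q, k) {
  apply(Q, 1, function(q) {
    d <- sqrt(colSums((t(X) - q)^2))
    nn <- order(d)[1:k]   # order() is stable: distance ties -> lower index
    cnt <- vapply(0:2, function(cl) sum(y[nn] == cl), integer(1))
    top <- (0:2)[cnt == max(cnt)]
    if (length(top) > 1) {
      sums <- vapply(top, function(cl) sum(d[nn][y[nn] == cl]), numeric(1))
      top <- top[sums == min(sums)]
    }
    if (length(top) > 1) {
      for (i in nn) if (y[i] %in% top) { top <- y[i]; break }
    }
    top
  })
}
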