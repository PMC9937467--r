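// Dynamic-programming kernels: exact DTW, multilevel FastDTW, sliding-window
// template scoring, and k-nearest-neighbour search with a deterministic
// tie-break chain.  Kept in C++ because a session yields tens of thousands of
// window/template alignments and ~1e9 query-train distance pairs.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <utility>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct PathDP {
  double cost;
  std::vector<std::pair<int, int> > path;  // (i, j), 0-based, (0,0) .. (n-1,m-1)
};

// DP restricted to a corridor lo[i]..hi[i] (inclusive, 0-based).  Local cost
// |a_i - b_j|; symmetric step pattern (diag / up / left, weight 1 each);
// boundary-anchored.  The corridor must contain (0,0), (n-1,m-1) and at least
// one monotone path (guaranteed for windows projected from a coarse path).
static PathDP dtw_window(const std::vector<double>& a,
                         const std::vector<double>& b,
                         const std::vector<int>& lo,
                         const std::vector<int>& hi,
                         bool want_path) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<std::vector<double> > cum(n);
  for (int i = 0; i < n; ++i) cum[i].assign(hi[i] - lo[i] + 1, INF);

#define CUM(i, j) \
  (((j) < lo[(i)] || (j) > hi[(i)]) ? INF : cum[(i)][(j) - lo[(i)]])

  for (int i = 0; i < n; ++i) {
    for (int j = lo[i]; j <= hi[i]; ++j) {
      const double d = std::fabs(a[i] - b[j]);
      double c;
      if (i == 0 && j == 0) {
        c = d;
      } else {
        double best = INF;
        if (i > 0 && j > 0) best = std::min(best, CUM(i - 1, j - 1));
        if (i > 0) best = std::min(best, CUM(i - 1, j));
        if (j > 0) best = std::min(best, CUM(i, j - 1));
        c = (best == INF) ? INF : d + best;
      }
      cum[i][j - lo[i]] = c;
    }
  }

  PathDP out;
  out.cost = CUM(n - 1, m - 1);
  if (want_path) {
    int i = n - 1, j = m - 1;
    out.path.push_back(std::make_pair(i, j));
    while (i > 0 || j > 0) {
      double diag = (i > 0 && j > 0) ? CUM(i - 1, j - 1) : INF;
      double up   = (i > 0) ? CUM(i - 1, j) : INF;
      double left = (j > 0) ? CUM(i, j - 1) : INF;
      // deterministic preference: diagonal, then row step, then column step
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left)            { --i; }
      else                            { --j; }
      out.path.push_back(std::make_pair(i, j));
    }
    std::reverse(out.path.begin(), out.path.end());
  }
#undef CUM
  return out;
}

static PathDP dtw_full(const std::vector<double>& a,
                       const std::vector<double>& b, bool want_path) {
  std::vector<int> lo(a.size(), 0), hi(a.size(), (int)b.size() - 1);
  return dtw_window(a, b, lo, hi, want_path);
}

// Coarsen by pairwise mean; an odd tail sample is carried through unchanged.
static std::vector<double> halve(const std::vector<double>& x) {
  std::vector<double> y;
  y.reserve((x.size() + 1) / 2);
  size_t i = 0;
  for (; i + 1 < x.size(); i += 2) y.push_back(0.5 * (x[i] + x[i + 1]));
  if (i < x.size()) y.push_back(x[i]);
  return y;
}

// Project a coarse path onto the fine grid and widen by `radius`.
static void expand_window(const std::vector<std::pair<int, int> >& lowpath,
                          int n, int m, int radius,
                          std::vector<int>& lo, std::vector<int>& hi) {
  std::vector<int> rawlo(n, m), rawhi(n, -1);
  for (size_t c = 0; c < lowpath.size(); ++c) {
    for (int di = 0; di < 2; ++di) {
      for (int dj = 0; dj < 2; ++dj) {
        const int i = 2 * lowpath[c].first + di;
        const int j = 2 * lowpath[c].second + dj;
        if (i < n && j < m) {
          rawlo[i] = std::min(rawlo[i], j);
          rawhi[i] = std::max(rawhi[i], j);
        }
      }
    }
  }
  lo.assign(n, 0);
  hi.assign(n, m - 1);
  for (int i = 0; i < n; ++i) {
    int l = m, h = -1;
    const int k0 = std::max(0, i - radius), k1 = std::min(n - 1, i + radius);
    for (int k = k0; k <= k1; ++k) {
      if (rawhi[k] < 0) continue;
      l = std::min(l, rawlo[k]);
      h = std::max(h, rawhi[k]);
    }
    lo[i] = std::max(0, l - radius);
    hi[i] = std::min(m - 1, h + radius);
  }
}

static PathDP fastdtw_rec(const std::vector<double>& a,
                          const std::vector<double>& b,
                          int radius, bool want_path) {
  const int n = (int)a.size(), m = (int)b.size();
  const int min_size = radius + 2;
  if (n < min_size || m < min_size) return dtw_full(a, b, want_path);
  std::vector<double> sa = halve(a), sb = halve(b);
  PathDP low = fastdtw_rec(sa, sb, radius, true);
  std::vector<int> lo, hi;
  expand_window(low.path, n, m, radius, lo, hi);
  return dtw_window(a, b, lo, hi, want_path);
}

static std::vector<double> as_vec(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

// [[Rcpp::export]]
double dtw_exact_cpp(NumericVector a, NumericVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("DTW requires non-empty series");
  return dtw_full(as_vec(a), as_vec(b), false).cost;
}

// [[Rcpp::export]]
double fastdtw_cpp(NumericVector a, NumericVector b, int radius) {
  if (a.size() == 0 || b.size() == 0)
    stop("DTW requires non-empty series");
  if (radius < 0) stop("radius must be >= 0");
  return fastdtw_rec(as_vec(a), as_vec(b), radius, false).cost;
}

// One FastDTW score per window position: starts 0, step, 2*step, ...
// while start + window <= length(x).
// [[Rcpp::export]]
NumericVector sliding_scores_cpp(NumericVector x, NumericVector tmpl,
                                 int window, int step, int radius) {
  const int n = x.size();
  if (window < 1 || step < 1) stop("window and step must be positive");
  if (n < window) stop("series shorter than one window");
  if (tmpl.size() == 0) stop("empty template");
  const int n_inst = (n - window) / step + 1;
  std::vector<double> tv = as_vec(tmpl);
  NumericVector out(n_inst);
  std::vector<double> w((size_t)window);
  for (int s = 0; s < n_inst; ++s) {
    const int start = s * step;
    std::copy(x.begin() + start, x.begin() + start + window, w.begin());
    out[s] = fastdtw_rec(w, tv, radius, false).cost;
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// KNN majority vote for every k in `ks` (labels in {0,1,2}), Euclidean
// distance.  Neighbour order is deterministic: distance, then train index.
// Vote ties: smaller summed Euclidean distance among tied classes, then the
// class of the nearest neighbour belonging to a tied class.
// [[Rcpp::export]]
IntegerMatrix knn_sweep_cpp(NumericMatrix trainX, IntegerVector trainY,
                            NumericMatrix queryX, IntegerVector ks) {
  const int ntr = trainX.nrow(), d = trainX.ncol();
  const int nq = queryX.nrow(), nk = ks.size();
  if (trainY.size() != ntr) stop("trainY length mismatch");
  if (queryX.ncol() != d) stop("query dimension mismatch");
  int kmax = 0;
  for (int i = 0; i < nk; ++i) {
    if (ks[i] < 1) stop("k must be >= 1");
    kmax = std::max(kmax, (int)ks[i]);
  }
  if (kmax > ntr) stop("k exceeds number of training points");
  for (int i = 0; i < ntr; ++i)
    if (trainY[i] < 0 || trainY[i] > 2) stop("labels must lie in {0,1,2}");

  // contiguous row-major copy of the training matrix
  std::vector<double> TR((size_t)ntr * d);
  for (int r = 0; r < ntr; ++r)
    for (int c = 0; c < d; ++c) TR[(size_t)r * d + c] = trainX(r, c);

  IntegerMatrix out(nq, nk);
  std::vector<std::pair<double, int> > top;
  std::vector<double> q((size_t)d);
  const bool d8 = (d == 8);
  for (int iq = 0; iq < nq; ++iq) {
    for (int c = 0; c < d; ++c) q[c] = queryX(iq, c);
    top.clear();
    double worst = INF;
    const double q0 = q[0], q1 = d > 1 ? q[1] : 0, q2 = d > 2 ? q[2] : 0,
                 q3 = d > 3 ? q[3] : 0, q4 = d > 4 ? q[4] : 0,
                 q5 = d > 5 ? q[5] : 0, q6 = d > 6 ? q[6] : 0,
                 q7 = d > 7 ? q[7] : 0;
    for (int r = 0; r < ntr; ++r) {
      const double* p = &TR[(size_t)r * d];
      double s;
      if (d8) {
        // unrolled 8-D distance with early abandonment at the half-way point
        const double a0 = q0 - p[0], a1 = q1 - p[1],
                     a2 = q2 - p[2], a3 = q3 - p[3];
        s = a0 * a0 + a1 * a1 + a2 * a2 + a3 * a3;
        if (s > worst) continue;
        const double a4 = q4 - p[4], a5 = q5 - p[5],
                     a6 = q6 - p[6], a7 = q7 - p[7];
        s += a4 * a4 + a5 * a5 + a6 * a6 + a7 * a7;
        if (s > worst) continue;
      } else {
        s = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = q[c] - p[c];
          s += diff * diff;
        }
        if ((int)top.size() == kmax && s > worst) continue;
      }
      std::pair<double, int> e(s, r);
      top.insert(std::upper_bound(top.begin(), top.end(), e), e);
      if ((int)top.size() > kmax) top.pop_back();
      if ((int)top.size() == kmax) worst = top.back().first;
    }
    for (int ki = 0; ki < nk; ++ki) {
      const int k = ks[ki];
      int counts[3] = {0, 0, 0};
      double sums[3] = {0.0, 0.0, 0.0};
      for (int i = 0; i < k; ++i) {
        const int lab = trainY[top[i].second];
        counts[lab] += 1;
        sums[lab] += std::sqrt(top[i].first);
      }
      int maxc = std::max(counts[0], std::max(counts[1], counts[2]));
      bool tied[3];
      int n_tied = 0;
      for (int lab = 0; lab < 3; ++lab) {
        tied[lab] = (counts[lab] == maxc && maxc > 0);
        if (tied[lab]) ++n_tied;
      }
      int winner = -1;
      if (n_tied == 1) {
        for (int lab = 0; lab < 3; ++lab)
          if (tied[lab]) winner = lab;
      } else {
        double best_sum = INF;
        int n_best = 0;
        for (int lab = 0; lab < 3; ++lab) {
          if (!tied[lab]) continue;
          if (sums[lab] < best_sum) { best_sum = sums[lab]; n_best = 1; winner = lab; }
          else if (sums[lab] == best_sum) { ++n_best; }
        }
        if (n_best > 1) {
          // nearest neighbour whose class is still tied on count and sum
          for (int i = 0; i < k; ++i) {
            const int lab = trainY[top[i].second];
            if (tied[lab] && sums[lab] == best_sum) { winner = lab; break; }
          }
        }
      }
      out(iq, ki) = winner;
    }
    if ((iq & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
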