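#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation kernels.
//
// The arc statistic for an arc of positions [i, j] (1-based, inclusive)
// against its complement within a window of n probes is the mean-difference
// statistic standardised to unit variance:
//
//   T(i, j) = |mean(arc) - mean(complement)| / sqrt(1/k + 1/(n - k))
//
// where k = j - i + 1.  The per-window variance is a common factor under
// permutation, so it is omitted; p-values come from permuting the window.
// Ties in the maximising arc are broken toward the smallest start, then the
// smallest end (leftmost, shortest), by strict-improvement updates in
// ascending (i, j) order.

namespace {

struct ArcHit {
  int i;
  int j;
  double stat;
};

inline double arc_stat(const std::vector<double>& cs, int i, int j, int n,
                       double total) {
  // cs[t] = sum of x[0..t-1]; arc covers 0-based [i-1, j-1]
  int k = j - i + 1;
  if (k <= 0 || k >= n) return -1.0;
  double s = cs[j] - cs[i - 1];
  double d = s / k - (total - s) / (n - k);
  return std::fabs(d) / std::sqrt(1.0 / k + 1.0 / (n - k));
}

ArcHit max_arc(const std::vector<double>& x, int min_width, bool exhaustive,
               int n_sample) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0);
  for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + x[t];
  double total = cs[n];

  ArcHit best = {0, 0, -1.0};
  if (exhaustive) {
    for (int i = 1; i <= n - min_width + 1; ++i) {
      // arc length in [min_width, n - min_width] keeps both sides wide enough
      int jmax = std::min(n, i - 1 + (n - min_width));
      for (int j = i + min_width - 1; j <= jmax; ++j) {
        double st = arc_stat(cs, i, j, n, total);
        if (st > best.stat) best = {i, j, st};
      }
    }
  } else {
    for (int s = 0; s < n_sample; ++s) {
      int i = 1 + (int)std::floor(unif_rand() * (n - min_width + 1));
      int j = i + min_width - 1 +
              (int)std::floor(unif_rand() * (n - (i + min_width - 1) + 1));
      if (j > n) j = n;
      int k = j - i + 1;
      if (k < min_width || n - k < min_width) continue;
      double st = arc_stat(cs, i, j, n, total);
      if (st > best.stat || (st == best.stat && (i < best.i || (i == best.i && j < best.j))))
        best = {i, j, st};
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".cbs_max_arc")]]
List cbs_max_arc_cpp(NumericVector x, int min_width, bool exhaustive,
                     int n_sample) {
  std::vector<double> xv(x.begin(), x.end());
  ArcHit best = max_arc(xv, min_width, exhaustive, n_sample);
  return List::create(_["i"] = best.i, _["j"] = best.j, _["stat"] = best.stat);
}

// Permutation p-value for an observed maximal arc statistic.  Stops early
// once the exceedance count guarantees p > alpha.  Returns (count + 1) /
// (done + 1) so that p is never exactly zero.
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
double cbs_perm_pvalue_cpp(NumericVector x, double obs_stat, int min_width,
                           int n_perm, double alpha, bool exhaustive,
                           int n_sample) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  int count = 0, done = 0;
  int stop_at = (int)std::ceil(alpha * (n_perm + 1));
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int t = n - 1; t > 0; --t) {
      int u = (int)std::floor(unif_rand() * (t + 1));
      std::swap(xv[t], xv[u]);
    }
    ArcHit hit = max_arc(xv, min_width, exhaustive, n_sample);
    ++done;
    if (hit.stat >= obs_stat - 1e-12) ++count;
    if (count + 1 > stop_at) break;  // p cannot fall below alpha any more
  }
  return (count + 1.0) / (done + 1.0);
}

// First-order Markov chain over the strong (G/C) vs weak (A/T) base classes.
// With probability rho the class of the previous base is copied, otherwise a
// fresh draw is taken with the local GC target p[t]; the stationary GC under
// a constant target p is p itself.  Uses R's RNG for seed reproducibility.
// [[Rcpp::export(name = ".markov_gc_classes")]]
IntegerVector markov_gc_classes_cpp(NumericVector p, double rho) {
  int n = p.size();
  IntegerVector cls(n);
  cls[0] = (unif_rand() < p[0]) ? 1 : 0;
  for (int t = 1; t < n; ++t) {
    if (unif_rand() < rho)
      cls[t] = cls[t - 1];
    else
      cls[t] = (unif_rand() < p[t]) ? 1 : 0;
  }
  return cls;
}
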