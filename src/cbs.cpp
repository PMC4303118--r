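// Circular binary segmentation core: the maximal circular two-segment
// t-statistic over all arcs of a probe series, and its permutation
// reference distribution. Kept in C++ because the permutation loop is
// O(n_perm * n^2); the R driver handles recursion and bookkeeping.
// Permutations draw from R's RNG so set.seed() controls them.

#include <Rcpp.h>
using namespace Rcpp;

// Max over arcs (i, j] (0 <= i < j <= n, min_width <= arc length <= n - min_width)
// of |mean_arc - mean_complement| / sqrt(1/k + 1/(n-k)). The complement wraps
// around the circularised segment, so edge arcs (i = 0 or j = n) propose a
// single change-point and interior arcs propose two.
static double max_stat(const std::vector<double>& s, int n, int min_width,
                       int* bi, int* bj) {
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int k = j - i;
      if (k < min_width || n - k < min_width) continue;
      double arc = s[j] - s[i];
      double rest = s[n] - arc;
      double diff = arc / k - rest / (n - k);
      double t = std::fabs(diff) / std::sqrt(1.0 / k + 1.0 / (n - k));
      if (t > best) {
        best = t;
        if (bi) *bi = i;
        if (bj) *bj = j;
      }
    }
  }
  return best;
}

static std::vector<double> prefix(const NumericVector& x) {
  int n = x.size();
  std::vector<double> s(n + 1, 0.0);
  for (int i = 0; i < n; ++i) s[i + 1] = s[i] + x[i];
  return s;
}

// [[Rcpp::export(name = ".cbs_max_stat")]]
List cbs_max_stat(NumericVector x, int min_width = 2) {
  int n = x.size(), bi = 0, bj = 0;
  std::vector<double> s = prefix(x);
  double best = max_stat(s, n, min_width, &bi, &bj);
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Permutation p-value for the observed max statistic, with early exit once
// p < alpha is no longer attainable. Returns (count + 1) / (n_done + 1).
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
double cbs_perm_pvalue(NumericVector x, double obs_stat, int n_perm,
                       double alpha, int min_width = 2) {
  int n = x.size();
  std::vector<double> work(x.begin(), x.end());
  int count = 0;
  int limit = (int)std::ceil(alpha * (n_perm + 1)) ;  // count+1 >= limit => fail
  RNGScope scope;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(work[i], work[j]);
    }
    std::vector<double> s(n + 1, 0.0);
    for (int i = 0; i < n; ++i) s[i + 1] = s[i] + work[i];
    double m = max_stat(s, n, min_width, nullptr, nullptr);
    if (m >= obs_stat) {
      ++count;
      if (count + 1 >= limit) return (double)(count + 1) / (b + 2);
    }
  }
  return (double)(count + 1) / (n_perm + 1);
}
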