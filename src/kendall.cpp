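#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Merge-sort inversion counter over y (already ordered by x, ties in x
// broken by y). O(n log n).
static long long count_inversions(std::vector<double>& y,
                                  std::vector<double>& buf,
                                  std::size_t lo, std::size_t hi) {
  if (hi - lo < 2) return 0;
  std::size_t mid = lo + (hi - lo) / 2;
  long long inv = count_inversions(y, buf, lo, mid) +
                  count_inversions(y, buf, mid, hi);
  std::size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {            // strict: ties are not inversions
      inv += static_cast<long long>(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi)  buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return inv;
}

static long long tie_pairs(std::vector<double> v) {
  std::sort(v.begin(), v.end());
  long long t = 0, run = 1;
  for (std::size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) { ++run; }
    else { t += run * (run - 1) / 2; run = 1; }
  }
  t += run * (run - 1) / 2;
  return t;
}

// Kendall tau-a of one pair: (concordant - discordant) / (n(n-1)/2),
// with tied pairs counting as neither. Knight's O(n log n) scheme:
// C - D = n0 - n1 - n2 + n3 - 2 * inversions, where n1/n2 are pairs
// tied in x / in y and n3 pairs tied in both.
static double tau_a_pair(const double* x, const double* y, int n) {
  std::vector<std::size_t> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](std::size_t a, std::size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> ys(n), buf(n);
  for (int i = 0; i < n; ++i) ys[i] = y[ord[i]];

  long long n0 = static_cast<long long>(n) * (n - 1) / 2;
  long long n1 = tie_pairs(std::vector<double>(x, x + n));
  long long n2 = tie_pairs(std::vector<double>(y, y + n));

  // pairs tied in both x and y
  std::vector<std::pair<double, double> > xy(n);
  for (int i = 0; i < n; ++i) xy[i] = std::make_pair(x[i], y[i]);
  std::sort(xy.begin(), xy.end());
  long long n3 = 0, run = 1;
  for (int i = 1; i < n; ++i) {
    if (xy[i] == xy[i - 1]) ++run;
    else { n3 += run * (run - 1) / 2; run = 1; }
  }
  n3 += run * (run - 1) / 2;

  long long inv = count_inversions(ys, buf, 0, static_cast<std::size_t>(n));
  long long con_minus_dis = n0 - n1 - n2 + n3 - 2 * inv;
  return static_cast<double>(con_minus_dis) / static_cast<double>(n0);
}

// [[Rcpp::export(name = ".kendall_tau_a_cpp")]]
double kendall_tau_a_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  return tau_a_pair(REAL(x), REAL(y), n);
}

// Pairwise tau-a matrix over the columns of X.
// [[Rcpp::export(name = ".kendall_tau_a_matrix_cpp")]]
NumericMatrix kendall_tau_a_matrix_cpp(NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericMatrix out(d, d);
  for (int j = 0; j < d; ++j) out(j, j) = 1.0;
  for (int j = 0; j < d; ++j) {
    for (int k = j + 1; k < d; ++k) {
      double t = tau_a_pair(&X(0, j), &X(0, k), n);
      out(j, k) = t;
      out(k, j) = t;
    }
  }
  return out;
}
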