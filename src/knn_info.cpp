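#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// k-NN information estimators on 1-D and paired 1-D samples.
// Neighbour searches exploit sorting along x; distances use the max-norm,
// for which the Kozachenko-Leonenko ball volume in d dimensions is (2*eps)^d.

namespace {

// distance to the k-th nearest neighbour of point i in a sorted 1-D array
double kth_dist_1d(const std::vector<double>& s, int i, int k) {
  const int n = static_cast<int>(s.size());
  int lo = i - 1, hi = i + 1;
  double eps = 0.0;
  for (int m = 0; m < k; ++m) {
    const double dlo = (lo >= 0) ? s[i] - s[lo] : R_PosInf;
    const double dhi = (hi < n) ? s[hi] - s[i] : R_PosInf;
    if (dlo <= dhi) { eps = dlo; --lo; } else { eps = dhi; ++hi; }
  }
  return eps;
}

// distance to the k-th nearest neighbour of point i under the max-norm in
// (x, y), where xs is sorted ascending and ys is aligned with xs.
double kth_dist_2d(const std::vector<double>& xs, const std::vector<double>& ys,
                   int i, int k) {
  const int n = static_cast<int>(xs.size());
  std::priority_queue<double> heap;  // k smallest max-norm distances
  int lo = i - 1, hi = i + 1;
  for (;;) {
    const double dlo = (lo >= 0) ? xs[i] - xs[lo] : R_PosInf;
    const double dhi = (hi < n) ? xs[hi] - xs[i] : R_PosInf;
    const double dnext = std::min(dlo, dhi);
    if (!R_finite(dnext)) break;
    if (static_cast<int>(heap.size()) == k && dnext >= heap.top()) break;
    int j;
    if (dlo <= dhi) { j = lo--; } else { j = hi++; }
    const double d = std::max(std::fabs(xs[i] - xs[j]), std::fabs(ys[i] - ys[j]));
    if (static_cast<int>(heap.size()) < k) heap.push(d);
    else if (d < heap.top()) { heap.pop(); heap.push(d); }
  }
  return heap.empty() ? 0.0 : heap.top();
}

// number of points j != i with |s[j] - s[i]| strictly below eps (s sorted)
int count_strict(const std::vector<double>& s, double centre, double eps) {
  const auto lo = std::upper_bound(s.begin(), s.end(), centre - eps);
  const auto hi = std::lower_bound(s.begin(), s.end(), centre + eps);
  int cnt = static_cast<int>(hi - lo) - 1;  // exclude the point itself
  return cnt < 0 ? 0 : cnt;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".kl_entropy_1d_nats")]]
double kl_entropy_1d_nats(NumericVector x, int k) {
  const int n = x.size();
  if (n < k + 1) stop("need at least k + 1 samples");
  std::vector<double> s(x.begin(), x.end());
  std::sort(s.begin(), s.end());
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double eps = kth_dist_1d(s, i, k);
    if (eps <= 0.0) eps = 1e-300;  // duplicated samples
    acc += std::log(2.0 * eps);
  }
  return -R::digamma(k) + R::digamma(n) + acc / n;
}

//' @noRd
// [[Rcpp::export(name = ".kl_entropy_2d_nats")]]
double kl_entropy_2d_nats(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (n < k + 1) stop("need at least k + 1 samples");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) { xs[i] = x[ord[i]]; ys[i] = y[ord[i]]; }
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double eps = kth_dist_2d(xs, ys, i, k);
    if (eps <= 0.0) eps = 1e-300;
    acc += 2.0 * std::log(2.0 * eps);
  }
  return -R::digamma(k) + R::digamma(n) + acc / n;
}

// Kraskov-Stoegbauer-Grassberger estimator (algorithm 1), in nats.
//' @noRd
// [[Rcpp::export(name = ".ksg_mi_nats")]]
double ksg_mi_nats(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (n < k + 1) stop("need at least k + 1 samples");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) { xs[i] = x[ord[i]]; ys[i] = y[ord[i]]; }
  std::vector<double> ysort(ys);
  std::sort(ysort.begin(), ysort.end());
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double eps = kth_dist_2d(xs, ys, i, k);
    const int nx = count_strict(xs, xs[i], eps);
    const int ny = count_strict(ysort, ys[i], eps);
    acc += R::digamma(nx + 1) + R::digamma(ny + 1);
  }
  return R::digamma(k) + R::digamma(n) - acc / n;
}
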