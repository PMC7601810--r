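#include <Rcpp.h>
#include <Rmath.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline double maxnorm_row(const NumericMatrix& m, int i, int j) {
  double d = 0.0;
  for (int c = 0; c < m.ncol(); ++c) {
    double v = std::fabs(m(i, c) - m(j, c));
    if (v > d) d = v;
  }
  return d;
}

// Kraskov-Stoegbauer-Grassberger mutual information, variant 1:
//   I = psi(k) + psi(N) - < psi(n_x + 1) + psi(n_y + 1) >
// where eps_i is the max-norm distance to the k-th nearest neighbor in the
// joint (x, y) space and n_x, n_y count marginal neighbors strictly within
// eps_i. Brute-force O(N^2) distances; N here is at most a few thousand.
// [[Rcpp::export]]
double cpp_ksg_mi(NumericMatrix x, NumericMatrix y, int k) {
  int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (n < k + 1) stop("need at least k + 1 samples");
  std::vector<double> dx(n), dy(n), dj(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) { dx[j] = R_PosInf; dy[j] = R_PosInf; dj[j] = R_PosInf; continue; }
      dx[j] = maxnorm_row(x, i, j);
      dy[j] = maxnorm_row(y, i, j);
      dj[j] = std::max(dx[j], dy[j]);
    }
    std::vector<double> tmp(dj);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
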