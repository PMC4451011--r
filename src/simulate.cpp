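#include <Rcpp.h>
using namespace Rcpp;

// Closed-loop linear-Gaussian simulation:
//   x_t    = P x_{t-1} + Lq e1_t          (AR(1) intention)
//   y_t    = A x_t + Lc e2_t              (neural channels)
//   xhat_t = F y_t + G xhat_{t-1}         (SSKF decode)
// Lq and Lc are lower-triangular Cholesky factors of Q and C (Q = Lq Lq',
// C = Lc Lc').  Uses the R RNG so runs are reproducible under set.seed().
// Long stationary runs back the analytic-vs-empirical MSE checks; the loop
// lives in C++ because a million-step recursion is the one place plain R
// is too slow.

static inline void matvec(const NumericMatrix& M, const std::vector<double>& v,
                          std::vector<double>& out) {
  int r = M.nrow(), c = M.ncol();
  for (int i = 0; i < r; ++i) {
    double s = 0.0;
    for (int j = 0; j < c; ++j) s += M(i, j) * v[j];
    out[i] = s;
  }
}

// [[Rcpp::export]]
List cpp_closed_loop_trace(NumericMatrix P, NumericMatrix Lq,
                           NumericMatrix A, NumericMatrix Lc,
                           NumericMatrix Fg, NumericMatrix G,
                           int T, NumericVector x0, NumericVector xhat0,
                           bool return_y = false) {
  int n = P.nrow(), k = A.nrow();
  NumericMatrix X(T, n), Xhat(T, n);
  NumericMatrix Y = return_y ? NumericMatrix(T, k) : NumericMatrix(0, 0);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xh(xhat0.begin(), xhat0.end());
  std::vector<double> tmp_n(n), tmp2_n(n), y(k), tmp_k(k), e(std::max(n, k));

  for (int t = 0; t < T; ++t) {
    // x = P x + Lq e
    matvec(P, x, tmp_n);
    for (int i = 0; i < n; ++i) e[i] = norm_rand();
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j <= i; ++j) s += Lq(i, j) * e[j];
      x[i] = tmp_n[i] + s;
    }
    // y = A x + Lc e
    matvec(A, x, y);
    for (int i = 0; i < k; ++i) e[i] = norm_rand();
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j <= i; ++j) s += Lc(i, j) * e[j];
      y[i] += s;
    }
    // xhat = F y + G xhat
    matvec(Fg, y, tmp_n);
    matvec(G, xh, tmp2_n);
    for (int i = 0; i < n; ++i) xh[i] = tmp_n[i] + tmp2_n[i];

    for (int i = 0; i < n; ++i) { X(t, i) = x[i]; Xhat(t, i) = xh[i]; }
    if (return_y) for (int i = 0; i < k; ++i) Y(t, i) = y[i];
  }

  List out = List::create(_["x"] = X, _["xhat"] = Xhat);
  if (return_y) out["y"] = Y;
  return out;
}
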