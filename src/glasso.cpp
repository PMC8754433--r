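// Graphical lasso core: block coordinate descent over columns of the
// covariance estimate W, each block solved by coordinate-descent lasso
// (Friedman, Hastie & Tibshirani 2008). Kept in C++ because the inner
// coordinate loop is inherently sequential.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".glasso_bcd")]]
List glasso_bcd(NumericMatrix S, double penalty, double tol, int max_iter) {
  const int p = S.nrow();
  NumericMatrix W(clone(S));
  for (int i = 0; i < p; ++i) W(i, i) += penalty;
  NumericMatrix B(p - 1, p); // per-column lasso coefficients
  double delta = R_PosInf;
  int it = 0;
  const double inner_tol = tol / 10.0;

  std::vector<int> idx(p - 1);
  std::vector<double> beta(p - 1);

  while (it < max_iter && delta >= tol) {
    ++it;
    delta = 0.0;
    for (int j = 0; j < p; ++j) {
      for (int k = 0, c = 0; k < p; ++k)
        if (k != j) idx[c++] = k;
      for (int k = 0; k < p - 1; ++k) beta[k] = B(k, j);

      // lasso: min 1/2 b' V b - u' b + penalty |b|_1, V = W[-j,-j], u = S[-j,j]
      for (int sweep = 0; sweep < 10000; ++sweep) {
        double bmax = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          const int rk = idx[k];
          double resid = S(rk, j);
          for (int l = 0; l < p - 1; ++l)
            if (l != k) resid -= W(rk, idx[l]) * beta[l];
          double bk = 0.0;
          if (resid > penalty)
            bk = (resid - penalty) / W(rk, rk);
          else if (resid < -penalty)
            bk = (resid + penalty) / W(rk, rk);
          const double ch = std::fabs(bk - beta[k]);
          if (ch > bmax) bmax = ch;
          beta[k] = bk;
        }
        if (bmax < inner_tol) break;
      }

      for (int k = 0; k < p - 1; ++k) B(k, j) = beta[k];
      for (int k = 0; k < p - 1; ++k) {
        const int rk = idx[k];
        double s = 0.0;
        for (int l = 0; l < p - 1; ++l) s += W(rk, idx[l]) * beta[l];
        const double ch = std::fabs(W(rk, j) - s);
        if (ch > delta) delta = ch;
        W(rk, j) = s;
        W(j, rk) = s;
      }
    }
  }

  // recover the precision matrix from the final (W, B) blocks
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0, c = 0; k < p; ++k) {
      if (k == j) continue;
      dot += W(k, j) * B(c++, j);
    }
    const double t22 = 1.0 / (W(j, j) - dot);
    Theta(j, j) = t22;
    for (int k = 0, c = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -B(c++, j) * t22;
    }
  }

  return List::create(_["W"] = W, _["Theta"] = Theta,
                      _["iterations"] = it, _["delta"] = delta);
}
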