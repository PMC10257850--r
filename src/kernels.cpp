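// Hot numeric kernels of the training loop: the fused ZINB
// log-likelihood/gradient pass and the Adam parameter update. Both are
// single-pass loops with no temporaries; everything else in the package
// stays in R matrix algebra.

#include <Rcpp.h>
using namespace Rcpp;

// Fused ZINB log-likelihood and derivatives.
//
// x: counts (n x d); pi, log_mu, mu: decoder outputs (n x d); v: per-gene
// dispersion (length d). Returns the total log-likelihood, elementwise
// d/dmu and d/dpi (entries at the probability floor masked to zero), and
// the per-gene column sum of d/dv.
// [[Rcpp::export(name = ".zinb_ll_grads_cpp")]]
List zinb_ll_grads_cpp(NumericMatrix x, NumericMatrix pi,
                       NumericMatrix log_mu, NumericMatrix mu,
                       NumericVector v, double floor_) {
  const int n = x.nrow(), d = x.ncol();
  const double log_floor = std::log(floor_);
  NumericMatrix d_mu(n, d), d_pi(n, d);
  NumericVector d_v(d);
  double ll_sum = 0.0;
  for (int j = 0; j < d; ++j) {
    const double vj = v[j];
    const double lgv = R::lgammafn(vj);
    const double dgv = R::digamma(vj);
    const double lvj = std::log(vj);
    double dv_acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = x(i, j), pij = pi(i, j), muij = mu(i, j);
      const double vm = vj + muij;
      const double log_vm = std::log(vm);
      const double lvvm = lvj - log_vm;
      const double nb0ll = vj * lvvm;
      double ll, dmu, dpi, dv;
      if (xi == 0.0) {
        const double nb0 = std::exp(nb0ll);
        double s = pij + (1.0 - pij) * nb0;
        if (s < floor_) s = floor_;
        ll = std::log(s);
        dpi = (1.0 - nb0) / s;
        dmu = -(1.0 - pij) * nb0 * vj / (vm * s);
        dv = (1.0 - pij) * nb0 * (lvvm + muij / vm) / s;
      } else {
        double omp = 1.0 - pij;
        if (omp < floor_) omp = floor_;
        ll = std::log(omp) + R::lgammafn(xi + vj) - R::lgammafn(xi + 1.0) -
             lgv + nb0ll + xi * (log_mu(i, j) - log_vm);
        dpi = -1.0 / omp;
        dmu = xi / muij - (xi + vj) / vm;
        dv = R::digamma(xi + vj) - dgv + lvvm + (muij - xi) / vm;
      }
      if (ll <= log_floor) {          // floored: constant loss, no gradient
        ll = log_floor;
        dmu = 0.0; dpi = 0.0; dv = 0.0;
      }
      ll_sum += ll;
      d_mu(i, j) = dmu;
      d_pi(i, j) = dpi;
      dv_acc += dv;
    }
    d_v[j] = dv_acc;
  }
  return List::create(_["ll_sum"] = ll_sum, _["d_mu"] = d_mu,
                      _["d_pi"] = d_pi, _["d_v_col"] = d_v);
}

// In-place Adam update on the flat parameter vector. p, m, v are owned
// exclusively by the training loop and are modified in place.
// [[Rcpp::export(name = ".adam_update_cpp")]]
void adam_update_cpp(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, int t, double lr, double beta1,
                     double beta2, double eps) {
  const int n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("length mismatch in Adam update");
  const double lr_t = lr * std::sqrt(1.0 - std::pow(beta2, t)) /
                      (1.0 - std::pow(beta1, t));
  for (int i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    p[i] -= lr_t * m[i] / (std::sqrt(v[i]) + eps);
  }
}
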