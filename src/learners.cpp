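#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ridge-penalised logistic objective and gradient in one pass over X.
// par = c(w_1..w_p, b); objective = 0.5 * ||w||^2 + C * sum_i log(1 + exp(-m_i))
// with m_i the signed margin of sample i. The intercept is unpenalised.
// [[Rcpp::export]]
List lr_obj_grad_cpp(NumericMatrix X, NumericVector y01, NumericVector par,
                     double C) {
  const int n = X.nrow(), p = X.ncol();
  const double b = par[p];
  std::vector<double> z(n, b);
  for (int j = 0; j < p; ++j) {
    const double wj = par[j];
    if (wj == 0.0) continue;
    const double *col = &X(0, j);
    for (int i = 0; i < n; ++i) z[i] += col[i] * wj;
  }
  double loss = 0.0;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    const double m = (y01[i] == 1.0) ? z[i] : -z[i];
    // log(1 + exp(-m)) computed stably for either sign of m
    loss += (m > 0.0) ? std::log1p(std::exp(-m)) : (std::log1p(std::exp(m)) - m);
    const double pr = 1.0 / (1.0 + std::exp(-z[i]));
    g[i] = C * (pr - y01[i]);
  }
  double pen = 0.0;
  NumericVector grad(p + 1);
  for (int j = 0; j < p; ++j) {
    const double *col = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += col[i] * g[i];
    grad[j] = par[j] + s;
    pen += par[j] * par[j];
  }
  double sb = 0.0;
  for (int i = 0; i < n; ++i) sb += g[i];
  grad[p] = sb;
  return List::create(_["value"] = 0.5 * pen + C * loss, _["grad"] = grad);
}

// Linear SVM trained by stochastic gradient descent on the hinge loss with an
// L2 penalty (Pegasos-style schedule eta_t = 1/(alpha * (t0 + t))). `order` is
// the 0-based visiting order over all epochs, drawn by the caller from a
// seeded RNG so the fit is reproducible. The iterates from step `avg_start`
// (0-based) onward are tail-averaged, which stabilises the solution the way
// averaged SGD implementations do. Weight shrinkage is carried in a scale
// factor so the O(p) inner update runs only on margin violations.
// [[Rcpp::export]]
List sgd_hinge_cpp(NumericMatrix X, NumericVector ypm1, double alpha,
                   IntegerVector order, int avg_start) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), wsum(p, 0.0);
  double b = 0.0, wscale = 1.0, bsum = 0.0;
  double n_avg = 0.0;
  // schedule offset keeps early steps at a typical-weight scale instead of
  // the 1/alpha blowup of the unshifted 1/(alpha*t) schedule
  const double typw = std::sqrt(1.0 / std::sqrt(alpha));
  const double t0 = 1.0 / (alpha * typw);
  for (R_xlen_t k = 0; k < order.size(); ++k) {
    const int i = order[k];
    const double t = t0 + static_cast<double>(k) + 1.0;
    const double eta = 1.0 / (alpha * t);
    double dot = 0.0;
    for (int j = 0; j < p; ++j) dot += X(i, j) * w[j];
    const double z = wscale * dot + b;
    wscale *= (1.0 - eta * alpha);
    if (wscale < 1e-10) {
      for (int j = 0; j < p; ++j) w[j] *= wscale;
      wscale = 1.0;
    }
    if (ypm1[i] * z < 1.0) {
      const double c = eta * ypm1[i] / wscale;
      for (int j = 0; j < p; ++j) w[j] += c * X(i, j);
      b += eta * ypm1[i];
    }
    if (k >= avg_start) {
      for (int j = 0; j < p; ++j) wsum[j] += wscale * w[j];
      bsum += b;
      n_avg += 1.0;
    }
  }
  NumericVector wout(p);
  if (n_avg > 0.0) {
    for (int j = 0; j < p; ++j) wout[j] = wsum[j] / n_avg;
    b = bsum / n_avg;
  } else {
    for (int j = 0; j < p; ++j) wout[j] = wscale * w[j];
  }
  return List::create(_["weights"] = wout, _["intercept"] = b);
}
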