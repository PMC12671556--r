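// FISTA proximal-gradient solver with backtracking line search and adaptive
// restart for L1-penalized M-estimation.  Two convex losses are supported:
//
//   kind = 0, weighted logistic:
//     f(b) = sum_i cw_i [ log(1 + e^{x_i'b}) - y_i x_i'b ]
//   kind = 1, calibrated propensity (exponential tilt), arm a, s = (-1)^a:
//     f(b) = sum_i cw_i gw_i [ (a - A_i) x_i'b + I(A_i = a) e^{s x_i'b} ]
//   (the derivative weight gw multiplies the whole bracket; only then does
//    the true propensity coefficient solve the population calibration
//    equation for every initial outcome fit)
//
// The penalty is lambda * sum_j pen_j |b_j| (pen_j = 0 leaves the intercept
// unpenalized).  Exponent arguments are clamped at +-30; the number of rows
// hitting the clamp in the final gradient evaluation is reported.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct LossSpec {
  int kind;
  int a;           // arm for kind 1
  const arma::mat& X;
  const arma::vec& y;   // y for logistic, A for calibrated
  const arma::vec& cw;  // per-row normalization weights
  const arma::vec& gw;  // gdot-tau weights (kind 1 only)
};

static double clamp30(double x, long& nclamp) {
  if (x > 30.0) { ++nclamp; return 30.0; }
  if (x < -30.0) { ++nclamp; return -30.0; }
  return x;
}

static double loss_val(const LossSpec& L, const arma::vec& b, long& nclamp) {
  arma::vec eta = L.X * b;
  double f = 0;
  if (L.kind == 0) {
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      double e = clamp30(eta[i], nclamp);
      // log(1+exp(e)) computed stably
      double l1p = e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
      f += L.cw[i] * (l1p - L.y[i] * eta[i]);
    }
  } else {
    double s = L.a == 1 ? -1.0 : 1.0;
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      double f_i = ((double)L.a - L.y[i]) * eta[i];
      if ((int)L.y[i] == L.a) f_i += std::exp(clamp30(s * eta[i], nclamp));
      f += L.cw[i] * L.gw[i] * f_i;
    }
  }
  return f;
}

static arma::vec loss_grad(const LossSpec& L, const arma::vec& b, long& nclamp) {
  arma::vec eta = L.X * b;
  arma::vec r(eta.n_elem);
  if (L.kind == 0) {
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      double p = 1.0 / (1.0 + std::exp(-clamp30(eta[i], nclamp)));
      r[i] = L.cw[i] * (p - L.y[i]);
    }
  } else {
    double s = L.a == 1 ? -1.0 : 1.0;
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      double gi = (double)L.a - L.y[i];
      if ((int)L.y[i] == L.a) gi += s * std::exp(clamp30(s * eta[i], nclamp));
      r[i] = L.cw[i] * L.gw[i] * gi;
    }
  }
  return L.X.t() * r;
}

static arma::vec prox_l1(const arma::vec& v, const arma::vec& thr) {
  arma::vec out(v.n_elem);
  for (arma::uword j = 0; j < v.n_elem; ++j) {
    double t = thr[j];
    if (v[j] > t) out[j] = v[j] - t;
    else if (v[j] < -t) out[j] = v[j] + t;
    else out[j] = 0;
  }
  return out;
}

static double kkt_residual(const arma::vec& grad, const arma::vec& b,
                           double lambda, const arma::vec& pen) {
  double worst = 0;
  for (arma::uword j = 0; j < b.n_elem; ++j) {
    double lam = lambda * pen[j];
    double r;
    if (lam == 0) r = std::fabs(grad[j]);
    else if (b[j] != 0) r = std::fabs(grad[j] + lam * (b[j] > 0 ? 1.0 : -1.0));
    else r = std::max(std::fabs(grad[j]) - lam, 0.0);
    if (r > worst) worst = r;
  }
  return worst;
}

// [[Rcpp::export]]
List cpp_prox_lasso(const arma::mat& X, const arma::vec& y,
                    const arma::vec& cw, const arma::vec& gw,
                    int kind, int a, double lambda, const arma::vec& pen,
                    const arma::vec& coef0, int maxit, double tol) {
  LossSpec L{kind, a, X, y, cw, gw};
  long nclamp = 0;
  arma::vec b = coef0, z = coef0, b_old = coef0;
  double t = 1.0, Lip = 1.0;
  double fz = loss_val(L, z, nclamp);
  arma::vec gz = loss_grad(L, z, nclamp);
  double kkt = kkt_residual(gz, b, lambda, pen);
  int it = 0;
  arma::vec thr = lambda * pen;
  for (it = 0; it < maxit && kkt > tol; ++it) {
    // backtracking on the majorization at z
    arma::vec b_new;
    for (int bt = 0; bt < 60; ++bt) {
      b_new = prox_l1(z - gz / Lip, thr / Lip);
      arma::vec d = b_new - z;
      double q = fz + arma::dot(gz, d) + 0.5 * Lip * arma::dot(d, d);
      long dummy = 0;
      double fn = loss_val(L, b_new, dummy);
      if (fn <= q + 1e-12 * std::fabs(q)) break;
      Lip *= 2.0;
    }
    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
    arma::vec z_new = b_new + ((t - 1.0) / t_new) * (b_new - b_old);
    // adaptive restart: drop momentum when it points uphill
    if (arma::dot(z - b_new, b_new - b_old) > 0) {
      z_new = b_new;
      t_new = 1.0;
    }
    b_old = b;
    b = b_new;
    z = z_new;
    t = t_new;
    // divergence guard: the calibrated loss is unbounded below when the
    // penalty is too small to tame the exponential term
    if (!b.is_finite() || arma::abs(b).max() > 1e6) {
      long d2 = 0;
      arma::vec gdiv = loss_grad(L, b, d2);
      return List::create(_["coef"] = b,
                          _["kkt"] = kkt_residual(gdiv, b, lambda, pen),
                          _["iter"] = it, _["converged"] = false,
                          _["objective"] = R_NegInf,
                          _["n_clamped"] = (double)nclamp);
    }
    fz = loss_val(L, z, nclamp);
    gz = loss_grad(L, z, nclamp);
    if (it % 5 == 4 || arma::abs(b - b_old).max() < 1e-13) {
      long dummy = 0;
      arma::vec gb = loss_grad(L, b, dummy);
      kkt = kkt_residual(gb, b, lambda, pen);
      Lip = std::max(Lip * 0.9, 1e-10);  // allow step growth
    }
  }
  long dummy = 0;
  arma::vec gb = loss_grad(L, b, dummy);
  kkt = kkt_residual(gb, b, lambda, pen);
  double obj = loss_val(L, b, dummy) + lambda * arma::dot(pen, arma::abs(b));
  return List::create(_["coef"] = b, _["kkt"] = kkt, _["iter"] = it,
                      _["converged"] = (kkt <= tol), _["objective"] = obj,
                      _["n_clamped"] = (double)nclamp);
}
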