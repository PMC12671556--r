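// Fast logistic regression on tensor-product piecewise-linear (order-1)
// B-spline bases.  Order-1 bases have at most 2 non-zero functions per
// dimension at any point, so a row of the tensor design has 2^D non-zeros;
// the normal equations are assembled in O(n 4^D) independent of the basis
// dimension, which makes exhaustive degree selection by cross-validation
// affordable.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clamp30(double x) {
  if (x > 30.0) return 30.0;
  if (x < -30.0) return -30.0;
  return x;
}

struct SparseBasis {
  // for each row: 2^D column indices and weights
  arma::umat cols;   // n x m, m = 2^D
  arma::mat  wts;    // n x m
  arma::uword ncol;  // (d+1)^D
};

// Build the order-1 tensor basis in sparse row form.  Inputs are clamped to
// the boundary box [lo, hi] (extrapolation uses the boundary value).
static SparseBasis build_basis(const arma::mat& X, int degree,
                               const arma::rowvec& lo, const arma::rowvec& hi) {
  const arma::uword n = X.n_rows, D = X.n_cols;
  const arma::uword m = (arma::uword)1 << D;
  const arma::uword pd = (arma::uword)degree + 1;  // basis funcs per dim
  SparseBasis B;
  B.cols.set_size(n, m);
  B.wts.set_size(n, m);
  arma::uword C = 1;
  for (arma::uword d = 0; d < D; ++d) C *= pd;
  B.ncol = C;
  std::vector<arma::uword> idx(D);
  std::vector<double> fr(D);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword d = 0; d < D; ++d) {
      double range = hi[d] - lo[d];
      double t = range > 0 ? (X(i, d) - lo[d]) / range : 0.5;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      double u = t * degree;
      arma::uword j = (arma::uword)std::floor(u);
      if (j >= (arma::uword)degree) j = degree - 1;  // degree >= 1
      idx[d] = j;
      fr[d] = u - (double)j;
    }
    for (arma::uword c = 0; c < m; ++c) {
      arma::uword col = 0;
      double w = 1.0;
      arma::uword stride = 1;
      for (arma::uword d = 0; d < D; ++d) {
        arma::uword bit = (c >> d) & 1u;
        col += (idx[d] + bit) * stride;
        w *= bit ? fr[d] : (1.0 - fr[d]);
        stride *= pd;
      }
      B.cols(i, c) = col;
      B.wts(i, c) = w;
    }
  }
  return B;
}

// IRLS logistic fit on a row subset of a sparse basis.  Returns coefficients;
// a small ridge keeps the system solvable under empty cells or separation.
static arma::vec irls_fit(const SparseBasis& B, const arma::vec& y,
                          const arma::uvec& rows, double ridge, int maxit) {
  const arma::uword C = B.ncol, m = B.cols.n_cols;
  arma::vec coef(C, arma::fill::zeros);
  arma::vec eta(rows.n_elem, arma::fill::zeros);
  double ridge_abs = ridge * (double)rows.n_elem + 1e-10;
  arma::mat G(C, C);
  arma::vec rhs(C);
  for (int it = 0; it < maxit; ++it) {
    G.zeros();
    rhs.zeros();
    for (arma::uword r = 0; r < rows.n_elem; ++r) {
      arma::uword i = rows[r];
      double e = clamp30(eta[r]);
      double p = 1.0 / (1.0 + std::exp(-e));
      double w = p * (1.0 - p);
      if (w < 1e-6) w = 1e-6;
      double z = eta[r] + (y[i] - p) / w;
      double wz = w * z;
      for (arma::uword c1 = 0; c1 < m; ++c1) {
        arma::uword j1 = B.cols(i, c1);
        double b1 = B.wts(i, c1);
        if (b1 == 0) continue;
        rhs[j1] += b1 * wz;
        double wb1 = w * b1;
        for (arma::uword c2 = 0; c2 < m; ++c2) {
          double b2 = B.wts(i, c2);
          if (b2 == 0) continue;
          G(j1, B.cols(i, c2)) += wb1 * b2;
        }
      }
    }
    G.diag() += ridge_abs;
    arma::vec coef_new;
    bool ok = arma::solve(coef_new, G, rhs, arma::solve_opts::likely_sympd);
    if (!ok) {
      G.diag() += 1e-4 * (double)rows.n_elem;
      arma::solve(coef_new, G, rhs);
    }
    double delta = arma::abs(coef_new - coef).max();
    coef = coef_new;
    // refresh linear predictor
    for (arma::uword r = 0; r < rows.n_elem; ++r) {
      arma::uword i = rows[r];
      double e = 0;
      for (arma::uword c = 0; c < m; ++c) e += B.wts(i, c) * coef[B.cols(i, c)];
      eta[r] = e;
    }
    if (delta < 1e-6) break;
  }
  return coef;
}

static arma::vec basis_eta(const SparseBasis& B, const arma::vec& coef,
                           const arma::uvec& rows) {
  arma::vec eta(rows.n_elem);
  for (arma::uword r = 0; r < rows.n_elem; ++r) {
    arma::uword i = rows[r];
    double e = 0;
    for (arma::uword c = 0; c < B.cols.n_cols; ++c)
      e += B.wts(i, c) * coef[B.cols(i, c)];
    eta[r] = e;
  }
  return eta;
}

// Mean out-of-fold binomial entropy for each candidate common degree.
// foldid is 1-based with nfolds folds; boundaries are the column ranges of X.
// [[Rcpp::export]]
NumericVector cpp_spline_cv(const arma::mat& X, const arma::vec& y,
                            const IntegerVector& degrees,
                            const IntegerVector& foldid, int nfolds,
                            double ridge, int maxit) {
  const arma::uword n = X.n_rows;
  arma::rowvec lo = arma::min(X, 0), hi = arma::max(X, 0);
  NumericVector out(degrees.size());
  for (int g = 0; g < degrees.size(); ++g) {
    SparseBasis B = build_basis(X, degrees[g], lo, hi);
    double tot = 0;
    arma::uword ntot = 0;
    for (int f = 1; f <= nfolds; ++f) {
      std::vector<arma::uword> tr, te;
      for (arma::uword i = 0; i < n; ++i)
        (foldid[i] == f ? te : tr).push_back(i);
      if (te.empty() || tr.empty()) continue;
      arma::uvec trv(tr), tev(te);
      arma::vec coef = irls_fit(B, y, trv, ridge, maxit);
      arma::vec eta = basis_eta(B, coef, tev);
      for (arma::uword r = 0; r < tev.n_elem; ++r) {
        double p = 1.0 / (1.0 + std::exp(-clamp30(eta[r])));
        if (p < 1e-9) p = 1e-9;
        if (p > 1 - 1e-9) p = 1 - 1e-9;
        double yy = y[tev[r]];
        tot += -(yy * std::log(p) + (1 - yy) * std::log(1 - p));
      }
      ntot += tev.n_elem;
    }
    out[g] = ntot > 0 ? tot / (double)ntot : R_PosInf;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_spline_fit(const arma::mat& X, const arma::vec& y, int degree,
                    const arma::rowvec& lo, const arma::rowvec& hi,
                    double ridge, int maxit) {
  SparseBasis B = build_basis(X, degree, lo, hi);
  arma::uvec rows = arma::regspace<arma::uvec>(0, X.n_rows - 1);
  arma::vec coef = irls_fit(B, y, rows, ridge, maxit);
  return List::create(_["coef"] = coef);
}

// [[Rcpp::export]]
arma::vec cpp_spline_predict(const arma::mat& X, const arma::vec& coef,
                             int degree, const arma::rowvec& lo,
                             const arma::rowvec& hi) {
  SparseBasis B = build_basis(X, degree, lo, hi);
  arma::uvec rows = arma::regspace<arma::uvec>(0, X.n_rows - 1);
  arma::vec eta = basis_eta(B, coef, rows);
  arma::vec p(eta.n_elem);
  for (arma::uword i = 0; i < eta.n_elem; ++i)
    p[i] = 1.0 / (1.0 + std::exp(-clamp30(eta[i])));
  return p;
}
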