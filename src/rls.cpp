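#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exponentially weighted recursive least squares for an AR(n) model.
//
// State: coefficient estimate a (n x 1), inverse correlation matrix P (n x n),
// initialized a = 0, P = delta * I. For each sample k (0-based, k >= n):
//   phi    = [x[k-1], ..., x[k-n]]'
//   eps    = x[k] - phi' a              (a priori prediction error)
//   kgain  = P phi / (lambda + phi' P phi)
//   P      = (P - kgain phi' P) / lambda
//   a      = a + kgain * eps
//   xhat[k] = phi' a_prev = x[k] - eps
// The first n samples of xhat are copied from the input (no prediction
// history exists there). P is kept symmetric by explicit symmetrization;
// loss of positive-definiteness (non-positive denominator) aborts.
// [[Rcpp::export]]
List rls_core(const arma::vec& x, int n, double lambda, double delta,
              bool want_traj) {
  const int N = x.n_elem;
  if (N <= n) stop("segment must be longer than the model order");
  if (!x.is_finite()) stop("non-finite input");

  arma::vec a(n, arma::fill::zeros);
  arma::mat P(n, n, arma::fill::eye);
  P *= delta;
  arma::vec xhat = x;          // first n samples copied from input
  arma::mat traj;
  if (want_traj) traj.zeros(N, n);

  arma::vec phi(n), Pphi(n), kgain(n);
  for (int k = n; k < N; ++k) {
    for (int j = 0; j < n; ++j) phi[j] = x[k - 1 - j];
    double eps = x[k] - arma::dot(phi, a);
    xhat[k] = x[k] - eps;
    Pphi = P * phi;
    double denom = lambda + arma::dot(phi, Pphi);
    if (!(denom > 0.0) || !std::isfinite(denom))
      stop("RLS numerical breakdown: P lost positive-definiteness at sample %d (denom = %g)",
           k + 1, denom);
    kgain = Pphi / denom;
    P = (P - kgain * Pphi.t()) / lambda;
    P = 0.5 * (P + P.t());
    a += kgain * eps;
    if (want_traj) traj.row(k) = a.t();
  }

  List out = List::create(Named("est") = xhat, Named("coefficients") = a);
  if (want_traj) out["trajectory"] = traj;
  return out;
}

// Run RLS over every column of a matrix of segments, returning the
// one-step-ahead estimates (same shape). Fresh state per column.
// [[Rcpp::export]]
arma::mat rls_segments(const arma::mat& segs, int n, double lambda, double delta) {
  arma::mat out(segs.n_rows, segs.n_cols);
  for (arma::uword c = 0; c < segs.n_cols; ++c) {
    List r = rls_core(segs.col(c), n, lambda, delta, false);
    out.col(c) = as<arma::vec>(r["est"]);
  }
  return out;
}
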