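// Coupled-dipole (DDA) solver.  The dense interaction matrix
//   A = diag(alpha_i^{-1}) - G,  G_ij = free-space dyadic Green blocks
// is assembled once per geometry/material and the system A p = E_inc is
// solved per right-hand side with Jacobi-preconditioned BiCGSTAB.
// Gaussian units, wavenumber k of the embedding medium.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void green_block(const rowvec& ri, const rowvec& rj, double k,
                        cx_mat33& out) {
  rowvec d = ri - rj;
  double r = norm(d);
  rowvec u = d / r;
  mat33 uu = u.t() * u;
  mat33 I(fill::eye);
  std::complex<double> ikr(0.0, k * r);
  std::complex<double> ph = std::exp(ikr);
  std::complex<double> near = 1.0 / (r * r * r) -
    std::complex<double>(0.0, k / (r * r));
  cx_mat33 g = ph * (k * k / r * cx_mat33(I - uu, mat33(fill::zeros)) +
                     near * cx_mat33(3.0 * uu - I, mat33(fill::zeros)));
  out = g;
}

// [[Rcpp::export]]
Rcpp::List dda_solve_cpp(const arma::mat& pos, const arma::cx_mat& alpha9,
                         double k, const arma::cx_mat& einc, double tol,
                         int max_iter) {
  const uword M = pos.n_rows;
  const uword N = 3 * M;
  cx_mat A(N, N, fill::zeros);
  cx_mat33 g;
  for (uword i = 0; i < M; ++i) {
    cx_mat33 ai;
    for (uword c = 0; c < 9; ++c) ai(c % 3, c / 3) = alpha9(i, c);
    A.submat(3 * i, 3 * i, 3 * i + 2, 3 * i + 2) = inv(ai);
    for (uword j = i + 1; j < M; ++j) {
      green_block(pos.row(i), pos.row(j), k, g);
      A.submat(3 * i, 3 * j, 3 * i + 2, 3 * j + 2) = -g;
      A.submat(3 * j, 3 * i, 3 * j + 2, 3 * i + 2) = -g.st();
    }
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }

  cx_vec dinv = 1.0 / A.diag();
  const uword nrhs = einc.n_cols;
  cx_mat P(N, nrhs, fill::zeros);
  Rcpp::IntegerVector iters(nrhs);
  Rcpp::NumericVector resid(nrhs);

  for (uword c = 0; c < nrhs; ++c) {
    cx_vec b = einc.col(c) % dinv;           // Jacobi-preconditioned system
    auto mv = [&](const cx_vec& v) -> cx_vec { return (A * v) % dinv; };
    double bn = norm(b);
    cx_vec x(N, fill::zeros), r = b, r0 = r;
    cx_vec p(N, fill::zeros), v(N, fill::zeros);
    std::complex<double> rho(1, 0), alpha_s(1, 0), omega(1, 0);
    int it = 0; double rn = bn;
    while (it < max_iter && rn > tol * bn) {
      std::complex<double> rho1 = cdot(r0, r);
      if (std::abs(rho1) < 1e-300) break;
      if (it == 0) {
        p = r;
      } else {
        std::complex<double> beta = (rho1 / rho) * (alpha_s / omega);
        p = r + beta * (p - omega * v);
      }
      v = mv(p);
      alpha_s = rho1 / cdot(r0, v);
      cx_vec s = r - alpha_s * v;
      if (norm(s) <= tol * bn) { x += alpha_s * p; r = s; rn = norm(r); ++it; break; }
      cx_vec t = mv(s);
      omega = cdot(t, s) / cdot(t, t);
      x += alpha_s * p + omega * s;
      r = s - omega * t;
      rho = rho1;
      rn = norm(r);
      ++it;
      if ((it & 15) == 0) Rcpp::checkUserInterrupt();
    }
    P.col(c) = x;
    iters[c] = it;
    resid[c] = rn / bn;
  }
  return Rcpp::List::create(Rcpp::_["p"] = P,
                            Rcpp::_["iterations"] = iters,
                            Rcpp::_["residual"] = resid);
}
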