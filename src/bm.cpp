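// Bloch-McConnell propagation for N-state CEST.
//
// State variables are ordered (Mx_1, My_1, Mz_1, ..., Mx_N, My_N, Mz_N, 1):
// one Bloch block per exchanging state plus a unit augmentation that carries
// the R1_i * p_i return-to-equilibrium terms, so the full evolution is a
// single homogeneous linear system of dimension 3N+1 and the equilibrium
// magnetization is stationary in the absence of RF.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// exp(A * t) %*% v
// [[Rcpp::export]]
arma::vec cpp_expm_vec(const arma::mat& A, double t, const arma::vec& v) {
  return expmat(A * t) * v;
}

// One full CEST profile for a single spin.
//
// K        : N x N microscopic rate matrix, convention dp/dt = K p
// pops     : equilibrium populations (state 1 = observed major state)
// omega_hz : per-state resonance offset from the carrier (Hz)
// r1, r2   : per-state longitudinal / transverse relaxation rates (s^-1)
// b1_hz    : RF field strength (Hz); RF phase along x (z <-> y nutation)
// tex      : saturation time (s)
//
// Returns I/I0 = Mz_major(tex) / p_major for each offset.
// [[Rcpp::export]]
arma::vec cpp_cest_profile(const arma::vec& offsets_hz,
                           const arma::mat& K,
                           const arma::vec& pops,
                           const arma::vec& omega_hz,
                           const arma::vec& r1,
                           const arma::vec& r2,
                           double b1_hz,
                           double tex) {
  const uword N = pops.n_elem;
  const uword dim = 3 * N + 1;
  const double w1 = 2.0 * M_PI * b1_hz;

  // Offset-independent part: relaxation, nutation, exchange, equilibrium
  // return.  The x-y precession entries are filled in per offset.
  mat A(dim, dim, fill::zeros);
  for (uword i = 0; i < N; ++i) {
    const uword xi = 3 * i, yi = 3 * i + 1, zi = 3 * i + 2;
    A(xi, xi) -= r2(i);
    A(yi, yi) -= r2(i);
    A(zi, zi) -= r1(i);
    A(yi, zi) += w1;
    A(zi, yi) -= w1;
    A(zi, dim - 1) = r1(i) * pops(i);
    for (uword j = 0; j < N; ++j) {  // exchange couples like components
      A(xi, 3 * j)     += K(i, j);
      A(yi, 3 * j + 1) += K(i, j);
      A(zi, 3 * j + 2) += K(i, j);
    }
  }

  vec v0(dim, fill::zeros);
  for (uword i = 0; i < N; ++i) v0(3 * i + 2) = pops(i);
  v0(dim - 1) = 1.0;

  vec out(offsets_hz.n_elem);
  for (uword k = 0; k < offsets_hz.n_elem; ++k) {
    mat Ak = A;
    for (uword i = 0; i < N; ++i) {
      const double om = 2.0 * M_PI * (omega_hz(i) - offsets_hz(k));
      Ak(3 * i, 3 * i + 1) -= om;
      Ak(3 * i + 1, 3 * i) += om;
    }
    const vec m = expmat(Ak * tex) * v0;
    out(k) = m(2) / pops(0);
  }
  return out;
}
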