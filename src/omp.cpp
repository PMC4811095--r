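// Batch orthogonal matching pursuit for complex-valued patches.
// Greedy atom selection by conjugate correlation |a_k^H r|, least-squares
// refit on the active set after every selection. Hot loop of the
// dictionary-learning step, hence in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: M x I patches, A: M x J unit-norm dictionary, tau: max atoms per column,
// stop when ||r|| <= max(tol_rel * ||x||, tol_abs). Returns dense J x I codes.
// [[Rcpp::export(name = ".omp_encode_cpp")]]
arma::cx_mat omp_encode_cpp(const arma::cx_mat& X, const arma::cx_mat& A,
                            const int tau, const double tol_rel,
                            const double tol_abs) {
  const uword M = A.n_rows, J = A.n_cols, I = X.n_cols;
  if (X.n_rows != M) Rcpp::stop("patch length does not match dictionary");
  const int kmax = std::min<uword>(tau, std::min(M, J));
  cx_mat G(J, I, fill::zeros);

  for (uword i = 0; i < I; ++i) {
    const cx_vec x = X.col(i);
    const double xn = norm(x);
    if (xn == 0.0) continue;
    const double tol = std::max(tol_rel * xn, tol_abs);
    if (xn <= tol) continue;

    cx_vec r = x;
    uvec sel(kmax);
    std::vector<bool> used(J, false);
    cx_mat As(M, kmax);
    cx_vec coef;
    int k = 0;
    while (k < kmax && norm(r) > tol) {
      const vec corr = abs(A.t() * r);  // .t() is conjugate transpose
      // argmax over unused atoms
      uword best = J; double bestv = -1.0;
      for (uword j = 0; j < J; ++j)
        if (!used[j] && corr(j) > bestv) { bestv = corr(j); best = j; }
      if (best == J || bestv <= 1e-14 * xn) break;
      used[best] = true;
      sel(k) = best;
      As.col(k) = A.col(best);
      ++k;
      // least-squares refit on the active set
      coef = solve(As.head_cols(k), x);
      r = x - As.head_cols(k) * coef;
    }
    for (int t = 0; t < k; ++t) G(sel(t), i) = coef(t);
  }
  return G;
}
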