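#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Kabsch-fitted RMSD between two centred n x 3 coordinate blocks.
// Proper rotations only: the smallest singular value flips sign when the
// optimal orthogonal map would be a reflection.
static double kabsch_rmsd(const arma::mat &a, const arma::mat &b) {
  arma::mat C = a.t() * b;                  // 3 x 3 cross-covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, C);
  arma::mat R = U * V.t();
  if (arma::det(R) < 0) {                   // proper rotations only
    arma::mat D = arma::eye(3, 3);
    D(2, 2) = -1.0;
    R = U * D * V.t();
  }
  // explicit residual: immune to the cancellation that affects the
  // eigenvalue shortcut for near-congruent frames
  arma::mat res = a * R - b;
  return std::sqrt(arma::accu(res % res) / a.n_rows);
}

// coords: n_sel x 3 x n_frames array (selection already applied)
// [[Rcpp::export]]
arma::mat cpp_pairwise_rmsd(const arma::cube &coords) {
  const arma::uword nf = coords.n_slices;
  std::vector<arma::mat> centred(nf);
  for (arma::uword i = 0; i < nf; ++i) {
    arma::mat x = coords.slice(i);
    x.each_row() -= arma::mean(x, 0);
    centred[i] = x;
  }
  arma::mat out(nf, nf, arma::fill::zeros);
  for (arma::uword i = 0; i + 1 < nf; ++i) {
    for (arma::uword j = i + 1; j < nf; ++j) {
      double r = kabsch_rmsd(centred[i], centred[j]);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
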