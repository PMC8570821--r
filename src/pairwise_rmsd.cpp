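#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Minimum pairwise RMSD after optimal rigid superposition (Kabsch, proper
// rotation enforced) for every conformer pair.  X is an n x 3 x M cube of
// the masked (C-alpha) coordinates.  The rotation is applied explicitly and
// the residual summed directly: computing rmsd^2 from the singular-value
// trace identity loses ~sqrt(eps)*||X|| to cancellation for near-identical
// conformers, which would spoil the near-zero entries.
// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(arma::cube X) {
  const arma::uword n = X.n_rows, M = X.n_slices;
  for (arma::uword i = 0; i < M; ++i) {
    arma::mat &Xi = X.slice(i);
    Xi.each_row() -= arma::mean(Xi, 0);
  }
  arma::mat D(M, M, arma::fill::zeros);
  arma::mat C(3, 3), U(3, 3), V(3, 3), R(3, 3);
  arma::vec s(3), d = {1.0, 1.0, 1.0};
  for (arma::uword i = 0; i + 1 < M; ++i) {
    for (arma::uword j = i + 1; j < M; ++j) {
      C = X.slice(i).t() * X.slice(j);
      if (!arma::svd(U, s, V, C, "std"))
        Rcpp::stop("SVD failed for conformer pair (%d, %d)", i + 1, j + 1);
      d(2) = (arma::det(U) * arma::det(V) < 0.0) ? -1.0 : 1.0;
      R = U * arma::diagmat(d) * V.t();
      double ss = arma::accu(arma::square(X.slice(i) * R - X.slice(j)));
      D(i, j) = D(j, i) = std::sqrt(ss / double(n));
    }
  }
  return D;
}
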