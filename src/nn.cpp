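// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Shared-MLP + max-pool discriminator forward pass over B stacked clouds of
// n points each (P is (B*n) x 3). Returns the per-point hidden layer (needed
// for backprop), the pooled global features, the 1-based argmax rows of the
// pooling, and the realness scores. Column-major segment scans keep the
// pooling cache friendly.
// [[Rcpp::export]]
List disc_forward_cpp(const arma::mat& P,
                      const arma::mat& A1, const arma::vec& c1,
                      const arma::mat& A2, const arma::vec& c2,
                      const arma::vec& v, double b0,
                      int n, int B) {
  arma::mat U1 = P * A1;
  U1.each_row() += c1.t();
  U1.clamp(0.0, arma::datum::inf);
  arma::mat U2 = U1 * A2;
  U2.each_row() += c2.t();
  U2.clamp(0.0, arma::datum::inf);

  const int f = (int)U2.n_cols;
  arma::mat g(B, f);
  IntegerMatrix amax(B, f);
  for (int j = 0; j < f; ++j) {
    const double* col = U2.colptr(j);
    for (int b = 0; b < B; ++b) {
      const int off = b * n;
      double best = col[off];
      int besti = 0;
      for (int i = 1; i < n; ++i) {
        if (col[off + i] > best) {
          best = col[off + i];
          besti = i;
        }
      }
      g(b, j) = best;
      amax(b, j) = off + besti + 1; // 1-based global row
    }
  }
  arma::vec scores = g * v + b0;
  return List::create(
    _["U1"] = U1, _["g"] = g, _["amax"] = amax, _["scores"] = scores
  );
}
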