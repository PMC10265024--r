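// Exact (O(n^2)) t-SNE used for the 2-D acoustic trait space. Deterministic:
// all randomness (the initial layout) is drawn in R and passed in.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gaussian input affinities with per-point bandwidths found by binary search
// on the target perplexity.
static mat input_affinities(const mat& D2, double perplexity) {
  const uword n = D2.n_rows;
  mat P(n, n, fill::zeros);
  const double log_perp = std::log(perplexity);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, beta_lo = -datum::inf, beta_hi = datum::inf;
    rowvec Di = D2.row(i);
    Di(i) = datum::inf;
    for (int it = 0; it < 64; ++it) {
      rowvec Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi) + 1e-300;
      double H = std::log(sumP) + beta * accu(Di.replace(datum::inf, 0.0) % Pi) / sumP;
      double diff = H - log_perp;
      if (std::fabs(diff) < 1e-5) { P.row(i) = Pi / sumP; break; }
      if (diff > 0) { beta_lo = beta; beta = std::isinf(beta_hi) ? beta * 2 : (beta + beta_hi) / 2; }
      else          { beta_hi = beta; beta = std::isinf(beta_lo) ? beta / 2 : (beta + beta_lo) / 2; }
      Pi = exp(-Di * beta); Pi(i) = 0.0;
      P.row(i) = Pi / (accu(Pi) + 1e-300);
    }
  }
  return P;
}

// [[Rcpp::export(name = ".tsne_exact")]]
arma::mat tsne_exact(const arma::mat& X, const arma::mat& Y0,
                     double perplexity, int max_iter,
                     double eta, double exaggeration, int exaggerate_iter) {
  const uword n = X.n_rows;
  // squared Euclidean distances in feature space
  colvec sq = sum(square(X), 1);
  mat D2 = repmat(sq, 1, n) + repmat(sq.t(), n, 1) - 2.0 * (X * X.t());
  D2.elem(find(D2 < 0)).zeros();

  mat P = input_affinities(D2, perplexity);
  P = (P + P.t()) / (2.0 * n);
  P.elem(find(P < 1e-300)).fill(1e-300);
  P /= accu(P);
  mat P_run = P * exaggeration;

  mat Y = Y0, dY(n, 2, fill::zeros), gains(n, 2, fill::ones);
  double momentum = 0.5;
  for (int iter = 0; iter < max_iter; ++iter) {
    if (iter == exaggerate_iter) P_run = P;
    if (iter == 250) momentum = 0.8;
    colvec ysq = sum(square(Y), 1);
    mat num = repmat(ysq, 1, n) + repmat(ysq.t(), n, 1) - 2.0 * (Y * Y.t());
    num = 1.0 / (1.0 + num);
    num.diag().zeros();
    double Zsum = accu(num) + 1e-300;
    mat Q = num / Zsum;
    Q.elem(find(Q < 1e-300)).fill(1e-300);
    mat L = (P_run - Q) % num;
    mat G = 4.0 * (diagmat(sum(L, 1)) - L) * Y;
    // adaptive gains as in the reference implementation
    for (uword k = 0; k < n * 2; ++k) {
      bool same = (G(k) > 0) == (dY(k) > 0);
      gains(k) = same ? std::max(0.01, gains(k) * 0.8) : gains(k) + 0.2;
    }
    dY = momentum * dY - eta * (gains % G);
    Y += dY;
    Y.each_row() -= mean(Y, 0);
  }
  return Y;
}
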