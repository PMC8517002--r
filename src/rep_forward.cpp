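// Fast inference path for the deep representation model: two stacked LSTM
// layers followed by the two fully-connected heads. Mirrors the reference
// R implementation exactly (no dropout at inference); equality of the two
// paths is asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// One LSTM layer over the whole batch; returns the hidden state sequence
// needed as input to the next layer (out), with gate layout [i | f | g | o].
static void lstm_layer(const std::vector<mat>& x_steps, const mat& W,
                       const mat& U, const rowvec& b, std::vector<mat>& out) {
  const uword Tn = x_steps.size();
  const uword B = x_steps[0].n_rows;
  const uword H = U.n_rows;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  out.resize(Tn);
  for (uword t = 0; t < Tn; ++t) {
    mat z = x_steps[t] * W + h * U;
    z.each_row() += b;
    mat i = sigm(z.cols(0, H - 1));
    mat f = sigm(z.cols(H, 2 * H - 1));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = sigm(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    out[t] = h;
  }
}

// [[Rcpp::export]]
Rcpp::List rep_forward_cpp(const arma::cube& x, const arma::mat& W1,
                           const arma::mat& U1, const arma::rowvec& b1,
                           const arma::mat& W2, const arma::mat& U2,
                           const arma::rowvec& b2, const arma::mat& fc1W,
                           const arma::rowvec& fc1b, const arma::vec& fc2W,
                           const double fc2b) {
  const uword Tn = x.n_slices;
  std::vector<mat> steps(Tn), h1, h2;
  for (uword t = 0; t < Tn; ++t) steps[t] = x.slice(t);
  lstm_layer(steps, W1, U1, b1, h1);
  lstm_layer(h1, W2, U2, b2, h2);
  mat a1 = h2[Tn - 1] * fc1W;
  a1.each_row() += fc1b;
  a1 = clamp(a1, 0.0, datum::inf);  // ReLU
  vec z2 = a1 * fc2W + fc2b;
  vec p = 1.0 / (1.0 + exp(-z2));
  return Rcpp::List::create(Rcpp::Named("p") = p,
                            Rcpp::Named("features") = a1);
}
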