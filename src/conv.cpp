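// 1D convolution tower over tree-ordered OTU embeddings.
// Hot path of training; everything else stays in R.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double act_fun(double x, int type) {
  if (type == 1) return x > 0 ? x : 0.0;       // relu
  if (type == 2) return std::tanh(x);          // tanh
  return x;                                    // identity
}
static inline double act_deriv(double x, int type) {
  if (type == 1) return x > 0 ? 1.0 : 0.0;
  if (type == 2) { double t = std::tanh(x); return 1.0 - t * t; }
  return 1.0;
}

// Build the (padded) present-OTU embedding matrix for one sample:
// rows of E at idx (1-based, canonical tree order), zero-padded to >= l rows.
static arma::mat sample_P(const arma::mat& E, const arma::uvec& idx, int l) {
  int p = idx.n_elem;
  int rows = std::max(p, l);
  arma::mat P(rows, E.n_cols, arma::fill::zeros);
  for (int i = 0; i < p; ++i) P.row(i) = E.row(idx[i] - 1);
  return P;
}

// Forward pass of the convolutional tower for a batch.
// E: m x d embeddings; idx_list: per-sample 1-based present-OTU indices;
// Wc: (l*d) x h filter matrix (window rows stacked: position-major, i.e.
// rows 1..d are window position 1, etc.); bc: h biases; act: 0/1/2.
// Returns fP (h x B), amax (h x B, 1-based window start of the max),
// zmax (h x B, pre-activation at the max).
// [[Rcpp::export]]
List conv_forward(const arma::mat& E, const List& idx_list,
                  const arma::mat& Wc, const arma::vec& bc,
                  int l, int act) {
  int B = idx_list.size();
  int h = Wc.n_cols;
  int d = E.n_cols;
  arma::mat fP(h, B), zmax(h, B);
  arma::imat amax(h, B);
  for (int b = 0; b < B; ++b) {
    arma::uvec idx = as<arma::uvec>(idx_list[b]);
    arma::mat P = sample_P(E, idx, l);
    int L = P.n_rows - l + 1;
    // windowed design matrix: L x (l*d)
    arma::mat Pw(L, l * d);
    for (int k = 0; k < l; ++k) {
      Pw.cols(k * d, (k + 1) * d - 1) = P.rows(k, k + L - 1);
    }
    arma::mat Z = Pw * Wc;           // L x h
    Z.each_row() += bc.t();
    for (int j = 0; j < h; ++j) {
      // monotone activations: argmax of act(Z) = argmax of Z
      arma::uword imax;
      double z = Z.col(j).max(imax);
      fP(j, b) = act_fun(z, act);
      amax(j, b) = imax + 1;
      zmax(j, b) = z;
    }
  }
  return List::create(_["fP"] = fP, _["amax"] = amax, _["zmax"] = zmax);
}

// Backward pass: gradient of the loss w.r.t. Wc and bc given dfP (h x B).
// Only the max window of each filter receives gradient.
// [[Rcpp::export]]
List conv_backward(const arma::mat& E, const List& idx_list,
                   const arma::mat& dfP, const arma::imat& amax,
                   const arma::mat& zmax, int l, int d, int act) {
  int B = idx_list.size();
  int h = dfP.n_rows;
  arma::mat dWc(l * d, h, arma::fill::zeros);
  arma::vec dbc(h, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::uvec idx = as<arma::uvec>(idx_list[b]);
    arma::mat P = sample_P(E, idx, l);
    for (int j = 0; j < h; ++j) {
      double g = dfP(j, b) * act_deriv(zmax(j, b), act);
      if (g == 0.0) continue;
      int i0 = amax(j, b) - 1;
      for (int k = 0; k < l; ++k) {
        dWc.col(j).subvec(k * d, (k + 1) * d - 1) += g * P.row(i0 + k).t();
      }
      dbc(j) += g;
    }
  }
  return List::create(_["dWc"] = dWc, _["dbc"] = dbc);
}
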