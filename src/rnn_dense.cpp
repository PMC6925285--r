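// Dense-input GRU layer for the transcriber's recurrent stack: full-sequence
// forward (optionally time-reversed) with caches, and BPTT returning input
// gradients so conv layers below can be trained.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

//' @noRd
// [[Rcpp::export(name = ".gru_dense_fwd_cpp")]]
List gru_dense_fwd(const arma::mat& X, const arma::mat& Wx, const arma::mat& Wh,
                   const arma::vec& b, bool reverse) {
  arma::mat Xi = reverse ? arma::fliplr(X) : X;
  int T = Xi.n_cols;
  int H = Wh.n_cols;
  arma::mat Hst(H, T + 1, arma::fill::zeros);
  arma::mat gates(3 * H, T);
  arma::mat ahn_c(H, T);
  for (int t = 0; t < T; ++t) {
    arma::vec h = Hst.col(t);
    arma::vec ax = Wx * Xi.col(t) + b;
    arma::vec ah = Wh * h;
    arma::vec r = sigm(ax.rows(0, H - 1) + ah.rows(0, H - 1));
    arma::vec z = sigm(ax.rows(H, 2 * H - 1) + ah.rows(H, 2 * H - 1));
    arma::vec ahn = ah.rows(2 * H, 3 * H - 1);
    arma::vec n = arma::tanh(ax.rows(2 * H, 3 * H - 1) + r % ahn);
    Hst.col(t + 1) = z % h + (1.0 - z) % n;
    gates.col(t) = arma::join_cols(r, arma::join_cols(z, n));
    ahn_c.col(t) = ahn;
  }
  arma::mat Y = Hst.cols(1, T);
  if (reverse) Y = arma::fliplr(Y);
  return List::create(_["Y"] = Y, _["Hst"] = Hst, _["gates"] = gates,
                      _["ahn"] = ahn_c);
}

//' @noRd
// [[Rcpp::export(name = ".gru_dense_bwd_cpp")]]
List gru_dense_bwd(const arma::mat& X, const arma::mat& Wx, const arma::mat& Wh,
                   const List& cache, const arma::mat& dY, bool reverse) {
  arma::mat Xi = reverse ? arma::fliplr(X) : X;
  arma::mat dYi = reverse ? arma::fliplr(dY) : dY;
  arma::mat Hst = cache["Hst"], gates = cache["gates"], ahn_c = cache["ahn"];
  int T = Xi.n_cols;
  int H = Wh.n_cols;
  arma::mat dWx(arma::size(Wx), arma::fill::zeros);
  arma::mat dWh(arma::size(Wh), arma::fill::zeros);
  arma::vec db(3 * H, arma::fill::zeros);
  arma::mat dX(arma::size(Xi), arma::fill::zeros);
  arma::vec dh(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dYi.col(t);
    arma::vec h_prev = Hst.col(t);
    arma::vec r = gates.col(t).rows(0, H - 1);
    arma::vec z = gates.col(t).rows(H, 2 * H - 1);
    arma::vec n = gates.col(t).rows(2 * H, 3 * H - 1);
    arma::vec ahn = ahn_c.col(t);
    arma::vec daz = dh % (h_prev - n) % z % (1.0 - z);
    arma::vec dn_pre = dh % (1.0 - z) % (1.0 - n % n);
    arma::vec dar = (dn_pre % ahn) % r % (1.0 - r);
    arma::vec da_x = arma::join_cols(dar, arma::join_cols(daz, dn_pre));
    arma::vec da_h = arma::join_cols(dar, arma::join_cols(daz, dn_pre % r));
    dWx += da_x * Xi.col(t).t();
    db += da_x;
    dWh += da_h * h_prev.t();
    dX.col(t) = Wx.t() * da_x;
    dh = Wh.t() * da_h + dh % z;
  }
  if (reverse) dX = arma::fliplr(dX);
  return List::create(_["dX"] = dX, _["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db);
}
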