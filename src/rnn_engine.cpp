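// Recurrent assessment engine: one-hot token input (realised as a column
// lookup into the input weight matrix), single recurrent layer (GRU, LSTM or
// simple tanh cell, optionally bidirectional), sigmoid head on the
// concatenated final-timestep outputs. Forward scoring and full BPTT
// gradients of the per-sample cross-entropy loss.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

enum CellType { GRU, LSTM, SIMPLE };

static CellType cell_from_string(const std::string& s) {
  if (s == "gru") return GRU;
  if (s == "lstm") return LSTM;
  if (s == "simple") return SIMPLE;
  stop("unknown cell type '%s'", s.c_str());
}

int gates_per_cell(CellType c) { return c == GRU ? 3 : (c == LSTM ? 4 : 1); }

// One direction over the token sequence. Tokens are 0-based ids.
struct DirCache {
  arma::mat H;      // H x (T+1), column 0 = h0 = 0
  arma::mat gates;  // G*H x T (activated gate values)
  arma::mat aux;    // GRU: ahn (H x T); LSTM: [c (H x (T+1)) | tanh_c (H x T)] packed separately
  arma::mat C;      // LSTM cell states H x (T+1)
  arma::mat tanhC;  // LSTM tanh(c_t) H x T
};

static DirCache dir_forward(const arma::uvec& toks, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b, CellType cell) {
  int T = toks.n_elem;
  int H = Wh.n_cols;
  DirCache cc;
  cc.H = arma::mat(H, T + 1, arma::fill::zeros);
  int G = gates_per_cell(cell);
  cc.gates = arma::mat(G * H, T);
  if (cell == GRU) cc.aux = arma::mat(H, T);
  if (cell == LSTM) {
    cc.C = arma::mat(H, T + 1, arma::fill::zeros);
    cc.tanhC = arma::mat(H, T);
  }
  for (int t = 0; t < T; ++t) {
    arma::vec h = cc.H.col(t);
    arma::vec ax = Wx.col(toks(t)) + b;
    arma::vec ah = Wh * h;
    if (cell == GRU) {
      arma::vec r = sigm(ax.rows(0, H - 1) + ah.rows(0, H - 1));
      arma::vec z = sigm(ax.rows(H, 2 * H - 1) + ah.rows(H, 2 * H - 1));
      arma::vec ahn = ah.rows(2 * H, 3 * H - 1);
      arma::vec n = arma::tanh(ax.rows(2 * H, 3 * H - 1) + r % ahn);
      cc.H.col(t + 1) = z % h + (1.0 - z) % n;
      cc.gates.col(t) = arma::join_cols(r, arma::join_cols(z, n));
      cc.aux.col(t) = ahn;
    } else if (cell == LSTM) {
      arma::vec a = ax + ah;
      arma::vec i = sigm(a.rows(0, H - 1));
      arma::vec f = sigm(a.rows(H, 2 * H - 1));
      arma::vec g = arma::tanh(a.rows(2 * H, 3 * H - 1));
      arma::vec o = sigm(a.rows(3 * H, 4 * H - 1));
      arma::vec c = f % cc.C.col(t) + i % g;
      cc.C.col(t + 1) = c;
      cc.tanhC.col(t) = arma::tanh(c);
      cc.H.col(t + 1) = o % cc.tanhC.col(t);
      cc.gates.col(t) = arma::join_cols(arma::join_cols(i, f), arma::join_cols(g, o));
    } else {
      cc.H.col(t + 1) = arma::tanh(ax + ah);
    }
  }
  return cc;
}

// BPTT for one direction. dH_out: H x T gradient on every timestep's output
// (the engine sets only the final column non-zero). Accumulates into
// dWx/dWh/db; returns nothing else (token input has no upstream).
static void dir_backward(const arma::uvec& toks, const arma::mat& Wx,
                         const arma::mat& Wh, CellType cell, const DirCache& cc,
                         const arma::mat& dH_out,
                         arma::mat& dWx, arma::mat& dWh, arma::vec& db) {
  int T = toks.n_elem;
  int H = Wh.n_cols;
  arma::vec dh(H, arma::fill::zeros);
  arma::vec dc(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dH_out.col(t);
    arma::vec h_prev = cc.H.col(t);
    if (cell == GRU) {
      arma::vec r = cc.gates.col(t).rows(0, H - 1);
      arma::vec z = cc.gates.col(t).rows(H, 2 * H - 1);
      arma::vec n = cc.gates.col(t).rows(2 * H, 3 * H - 1);
      arma::vec ahn = cc.aux.col(t);
      arma::vec daz = dh % (h_prev - n) % z % (1.0 - z);
      arma::vec dn_pre = dh % (1.0 - z) % (1.0 - n % n);
      arma::vec dar = (dn_pre % ahn) % r % (1.0 - r);
      arma::vec da_x = arma::join_cols(dar, arma::join_cols(daz, dn_pre));
      arma::vec da_h = arma::join_cols(dar, arma::join_cols(daz, dn_pre % r));
      dWx.col(toks(t)) += da_x;
      db += da_x;
      dWh += da_h * h_prev.t();
      dh = Wh.t() * da_h + dh % z;
    } else if (cell == LSTM) {
      arma::vec i = cc.gates.col(t).rows(0, H - 1);
      arma::vec f = cc.gates.col(t).rows(H, 2 * H - 1);
      arma::vec g = cc.gates.col(t).rows(2 * H, 3 * H - 1);
      arma::vec o = cc.gates.col(t).rows(3 * H, 4 * H - 1);
      arma::vec tc = cc.tanhC.col(t);
      arma::vec c_prev = cc.C.col(t);
      arma::vec do_ = dh % tc;
      dc += dh % o % (1.0 - tc % tc);
      arma::vec da = arma::join_cols(
        arma::join_cols(dc % g % i % (1.0 - i), dc % c_prev % f % (1.0 - f)),
        arma::join_cols(dc % i % (1.0 - g % g), do_ % o % (1.0 - o)));
      dWx.col(toks(t)) += da;
      db += da;
      dWh += da * h_prev.t();
      dh = Wh.t() * da;
      dc = dc % f;
    } else {
      arma::vec h = cc.H.col(t + 1);
      arma::vec da = dh % (1.0 - h % h);
      dWx.col(toks(t)) += da;
      db += da;
      dWh += da * h_prev.t();
      dh = Wh.t() * da;
    }
  }
}

// Final-state feature vector: concat of each direction's own last step.
static arma::vec engine_features(const arma::uvec& toks, const List& params,
                                 CellType cell, bool bidir,
                                 DirCache* fw_out = nullptr, DirCache* bw_out = nullptr) {
  arma::mat Wxf = params["Wx_f"], Whf = params["Wh_f"];
  arma::vec bf = params["b_f"];
  DirCache fw = dir_forward(toks, Wxf, Whf, bf, cell);
  int T = toks.n_elem;
  arma::vec y = fw.H.col(T);
  if (bidir) {
    arma::mat Wxb = params["Wx_b"], Whb = params["Wh_b"];
    arma::vec bb = params["b_b"];
    arma::uvec rtoks = arma::reverse(toks);
    DirCache bw = dir_forward(rtoks, Wxb, Whb, bb, cell);
    y = arma::join_cols(y, bw.H.col(T));
    if (bw_out) *bw_out = bw;
  }
  if (fw_out) *fw_out = fw;
  return y;
}

//' @noRd
// [[Rcpp::export(name = ".engine_score_cpp")]]
double engine_score_cpp(const arma::uvec& tokens, const List& params,
                        std::string cell, bool bidir) {
  CellType ct = cell_from_string(cell);
  arma::vec y = engine_features(tokens, params, ct, bidir);
  arma::rowvec W = params["W_head"];
  double b = as<double>(params["b_head"]);
  return 1.0 / (1.0 + std::exp(-(arma::dot(W, y) + b)));
}

//' Cross-entropy loss and gradients for one labelled sequence.
//' @noRd
// [[Rcpp::export(name = ".engine_grad_cpp")]]
List engine_grad_cpp(const arma::uvec& tokens, double label, const List& params,
                     std::string cell, bool bidir) {
  CellType ct = cell_from_string(cell);
  DirCache fw, bw;
  arma::vec y = engine_features(tokens, params, ct, bidir, &fw, &bw);
  arma::rowvec W = params["W_head"];
  double bh = as<double>(params["b_head"]);
  double s = 1.0 / (1.0 + std::exp(-(arma::dot(W, y) + bh)));
  double eps = 1e-12;
  double loss = -(label * std::log(s + eps) + (1.0 - label) * std::log(1.0 - s + eps));
  double dpre = s - label;

  int T = tokens.n_elem;
  arma::mat Wxf = params["Wx_f"], Whf = params["Wh_f"];
  int H = Whf.n_cols;
  arma::mat dWxf(arma::size(Wxf), arma::fill::zeros);
  arma::mat dWhf(arma::size(Whf), arma::fill::zeros);
  arma::vec dbf(Wxf.n_rows, arma::fill::zeros);
  arma::vec dy = W.t() * dpre;

  arma::mat dHf(H, T, arma::fill::zeros);
  dHf.col(T - 1) = dy.rows(0, H - 1);
  dir_backward(tokens, Wxf, Whf, ct, fw, dHf, dWxf, dWhf, dbf);

  List grads = List::create(
    _["Wx_f"] = dWxf, _["Wh_f"] = dWhf, _["b_f"] = dbf,
    _["W_head"] = arma::rowvec(dpre * y.t()), _["b_head"] = dpre);

  if (bidir) {
    arma::mat Wxb = params["Wx_b"], Whb = params["Wh_b"];
    arma::mat dWxb(arma::size(Wxb), arma::fill::zeros);
    arma::mat dWhb(arma::size(Whb), arma::fill::zeros);
    arma::vec dbb(Wxb.n_rows, arma::fill::zeros);
    arma::uvec rtoks = arma::reverse(tokens);
    arma::mat dHb(H, T, arma::fill::zeros);
    dHb.col(T - 1) = dy.rows(H, 2 * H - 1);
    dir_backward(rtoks, Wxb, Whb, ct, bw, dHb, dWxb, dWhb, dbb);
    grads["Wx_b"] = dWxb;
    grads["Wh_b"] = dWhb;
    grads["b_b"] = dbb;
  }
  return List::create(_["score"] = s, _["loss"] = loss, _["grads"] = grads);
}
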