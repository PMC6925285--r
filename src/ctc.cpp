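// Connectionist temporal classification: forward loss and analytic gradient.
// Log-domain alpha/beta recursions over the blank-extended target.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logsumexp2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double logsumexp3(double a, double b, double c) {
  return logsumexp2(logsumexp2(a, b), c);
}

// Extended label sequence: blank, l1, blank, l2, ..., lL, blank (length 2L+1).
static arma::ivec extend_target(const arma::ivec& target, int blank) {
  int L = target.n_elem;
  arma::ivec ext(2 * L + 1);
  for (int i = 0; i < L; ++i) {
    ext(2 * i) = blank;
    ext(2 * i + 1) = target(i);
  }
  ext(2 * L) = blank;
  return ext;
}

// Alpha recursion; returns full T x S alpha matrix (log domain).
static arma::mat ctc_alpha(const arma::mat& logp, const arma::ivec& ext, int blank) {
  int T = logp.n_rows, S = ext.n_elem;
  arma::mat alpha(T, S);
  alpha.fill(NEG_INF);
  alpha(0, 0) = logp(0, ext(0));
  if (S > 1) alpha(0, 1) = logp(0, ext(1));
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double a = alpha(t - 1, s);
      if (s >= 1) a = logsumexp2(a, alpha(t - 1, s - 1));
      if (s >= 2 && ext(s) != blank && ext(s) != ext(s - 2))
        a = logsumexp2(a, alpha(t - 1, s - 2));
      alpha(t, s) = a + logp(t, ext(s));
    }
  }
  return alpha;
}

static arma::mat ctc_beta(const arma::mat& logp, const arma::ivec& ext, int blank) {
  int T = logp.n_rows, S = ext.n_elem;
  arma::mat beta(T, S);
  beta.fill(NEG_INF);
  beta(T - 1, S - 1) = logp(T - 1, ext(S - 1));
  if (S > 1) beta(T - 1, S - 2) = logp(T - 1, ext(S - 2));
  for (int t = T - 2; t >= 0; --t) {
    for (int s = S - 1; s >= 0; --s) {
      double b = beta(t + 1, s);
      if (s + 1 < S) b = logsumexp2(b, beta(t + 1, s + 1));
      if (s + 2 < S && ext(s) != blank && ext(s) != ext(s + 2))
        b = logsumexp2(b, beta(t + 1, s + 2));
      beta(t, s) = b + logp(t, ext(s));
    }
  }
  return beta;
}

//' @noRd
// [[Rcpp::export(name = ".ctc_loss_cpp")]]
double ctc_loss_cpp(const arma::mat& logp, const arma::ivec& target, int blank) {
  int T = logp.n_rows;
  int L = target.n_elem;
  if (T == 0) return (L == 0) ? 0.0 : R_PosInf;
  arma::ivec ext = extend_target(target, blank);
  arma::mat alpha = ctc_alpha(logp, ext, blank);
  int S = ext.n_elem;
  double ll = (S > 1)
    ? logsumexp2(alpha(T - 1, S - 1), alpha(T - 1, S - 2))
    : alpha(T - 1, 0);
  if (ll == NEG_INF) return R_PosInf;
  return -ll;
}

//' Loss plus gradient with respect to pre-softmax logits.
//' @noRd
// [[Rcpp::export(name = ".ctc_grad_cpp")]]
List ctc_grad_cpp(const arma::mat& logits, const arma::ivec& target, int blank) {
  int T = logits.n_rows, C = logits.n_cols;
  int L = target.n_elem;
  if (T == 0) {
    return List::create(_["loss"] = (L == 0) ? 0.0 : R_PosInf,
                        _["grad"] = arma::mat(0, C));
  }
  // log-softmax rows
  arma::mat logp(T, C);
  for (int t = 0; t < T; ++t) {
    double m = logits.row(t).max();
    double z = std::log(arma::sum(arma::exp(logits.row(t) - m))) + m;
    logp.row(t) = logits.row(t) - z;
  }
  arma::ivec ext = extend_target(target, blank);
  int S = ext.n_elem;
  arma::mat alpha = ctc_alpha(logp, ext, blank);
  arma::mat beta = ctc_beta(logp, ext, blank);
  double ll = (S > 1)
    ? logsumexp2(alpha(T - 1, S - 1), alpha(T - 1, S - 2))
    : alpha(T - 1, 0);
  if (ll == NEG_INF) {
    return List::create(_["loss"] = R_PosInf, _["grad"] = arma::mat(T, C, arma::fill::zeros));
  }
  // gamma(t, k) = P(label k at frame t | target) ; grad = softmax - gamma
  arma::mat grad = arma::exp(logp);
  for (int t = 0; t < T; ++t) {
    arma::vec lg(C);
    lg.fill(NEG_INF);
    for (int s = 0; s < S; ++s) {
      // alpha*beta double-counts logp(t, ext(s)) once
      double v = alpha(t, s) + beta(t, s) - logp(t, ext(s));
      lg(ext(s)) = logsumexp2(lg(ext(s)), v);
    }
    for (int k = 0; k < C; ++k) {
      if (lg(k) != NEG_INF) grad(t, k) -= std::exp(lg(k) - ll);
    }
  }
  return List::create(_["loss"] = -ll, _["grad"] = grad);
}
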