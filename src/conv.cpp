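// 2D convolution (SAME padding, configurable stride) with per-channel batch
// normalisation before a clipped-ReLU activation, as used by the transcriber's
// front conv stack. Forward caches everything needed for the exact backward
// pass. Weight layout: cube(kt, kf, Cin*Cout), slice index ci + Cin*co.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int stride) { return (n + stride - 1) / stride; }

//' @noRd
// [[Rcpp::export(name = ".conv_bn_relu_fwd_cpp")]]
List conv_bn_relu_fwd(const arma::cube& X, const arma::cube& W, const arma::vec& b,
                      int c_out, int stride_t, int stride_f,
                      const arma::vec& gamma, const arma::vec& beta,
                      bool training, const arma::vec& run_mean,
                      const arma::vec& run_var, double eps, double relu_cap) {
  int T = X.n_rows, F = X.n_cols, c_in = X.n_slices;
  int kt = W.n_rows, kf = W.n_cols;
  int To = out_dim(T, stride_t), Fo = out_dim(F, stride_f);
  int pad_t = std::max((To - 1) * stride_t + kt - T, 0);
  int pad_f = std::max((Fo - 1) * stride_f + kf - F, 0);
  int pt = pad_t / 2, pf = pad_f / 2;

  arma::cube A(To, Fo, c_out, arma::fill::zeros);  // pre-BN conv output
  for (int co = 0; co < c_out; ++co) {
    for (int to = 0; to < To; ++to) {
      for (int fo = 0; fo < Fo; ++fo) {
        double acc = b(co);
        int t0 = to * stride_t - pt, f0 = fo * stride_f - pf;
        for (int ci = 0; ci < c_in; ++ci) {
          const arma::mat& Wk = W.slice(ci + c_in * co);
          for (int dt = 0; dt < kt; ++dt) {
            int ti = t0 + dt;
            if (ti < 0 || ti >= T) continue;
            for (int df = 0; df < kf; ++df) {
              int fi = f0 + df;
              if (fi < 0 || fi >= F) continue;
              acc += X(ti, fi, ci) * Wk(dt, df);
            }
          }
        }
        A(to, fo, co) = acc;
      }
    }
  }

  arma::vec mean(c_out), var(c_out);
  if (training) {
    for (int co = 0; co < c_out; ++co) {
      mean(co) = arma::mean(arma::vectorise(A.slice(co)));
      arma::vec v = arma::vectorise(A.slice(co)) - mean(co);
      var(co) = arma::dot(v, v) / v.n_elem;
    }
  } else {
    mean = run_mean;
    var = run_var;
  }
  arma::cube Xhat(To, Fo, c_out), Z(To, Fo, c_out), Y(To, Fo, c_out);
  for (int co = 0; co < c_out; ++co) {
    double inv_sd = 1.0 / std::sqrt(var(co) + eps);
    Xhat.slice(co) = (A.slice(co) - mean(co)) * inv_sd;
    Z.slice(co) = gamma(co) * Xhat.slice(co) + beta(co);
    Y.slice(co) = arma::clamp(Z.slice(co), 0.0, relu_cap);
  }
  return List::create(_["Y"] = Y, _["A"] = A, _["Xhat"] = Xhat, _["Z"] = Z,
                      _["mean"] = mean, _["var"] = var,
                      _["pt"] = pt, _["pf"] = pf);
}

//' @noRd
// [[Rcpp::export(name = ".conv_bn_relu_bwd_cpp")]]
List conv_bn_relu_bwd(const arma::cube& X, const arma::cube& W, int c_out,
                      int stride_t, int stride_f, const arma::vec& gamma,
                      const List& cache, const arma::cube& dY,
                      double eps, double relu_cap) {
  int T = X.n_rows, F = X.n_cols, c_in = X.n_slices;
  int kt = W.n_rows, kf = W.n_cols;
  arma::cube A = cache["A"], Xhat = cache["Xhat"], Z = cache["Z"];
  arma::vec mean = cache["mean"], var = cache["var"];
  int pt = as<int>(cache["pt"]), pf = as<int>(cache["pf"]);
  int To = A.n_rows, Fo = A.n_cols;
  double N = double(To) * double(Fo);

  // clipped-ReLU then batch-norm backward, per channel
  arma::cube dA(To, Fo, c_out);
  arma::vec dgamma(c_out), dbeta(c_out);
  for (int co = 0; co < c_out; ++co) {
    arma::mat mask = arma::conv_to<arma::mat>::from(
      (Z.slice(co) > 0.0) % (Z.slice(co) < relu_cap));
    arma::mat dZ = dY.slice(co) % mask;
    dgamma(co) = arma::accu(dZ % Xhat.slice(co));
    dbeta(co) = arma::accu(dZ);
    arma::mat dXhat = dZ * gamma(co);
    double inv_sd = 1.0 / std::sqrt(var(co) + eps);
    arma::mat Am = A.slice(co) - mean(co);
    double dvar = arma::accu(dXhat % Am) * (-0.5) * std::pow(var(co) + eps, -1.5);
    double dmean = -arma::accu(dXhat) * inv_sd - 2.0 * dvar * arma::accu(Am) / N;
    dA.slice(co) = dXhat * inv_sd + (2.0 * dvar / N) * Am + dmean / N;
  }

  arma::cube dW(arma::size(W), arma::fill::zeros);
  arma::vec db(c_out, arma::fill::zeros);
  arma::cube dX(arma::size(X), arma::fill::zeros);
  for (int co = 0; co < c_out; ++co) {
    db(co) = arma::accu(dA.slice(co));
    for (int to = 0; to < To; ++to) {
      for (int fo = 0; fo < Fo; ++fo) {
        double g = dA(to, fo, co);
        if (g == 0.0) continue;
        int t0 = to * stride_t - pt, f0 = fo * stride_f - pf;
        for (int ci = 0; ci < c_in; ++ci) {
          arma::mat& dWk = dW.slice(ci + c_in * co);
          const arma::mat& Wk = W.slice(ci + c_in * co);
          for (int dt = 0; dt < kt; ++dt) {
            int ti = t0 + dt;
            if (ti < 0 || ti >= T) continue;
            for (int df = 0; df < kf; ++df) {
              int fi = f0 + df;
              if (fi < 0 || fi >= F) continue;
              dWk(dt, df) += X(ti, fi, ci) * g;
              dX(ti, fi, ci) += Wk(dt, df) * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
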