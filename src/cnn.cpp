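// Small residual CNN over 48x32 log-Mel inputs.
//
// Activations are stored as C x (H*W*B) matrices (channels in rows, spatial
// positions of all batch samples in columns, sample-major with column-major
// spatial layout), so every convolution is an im2col gather followed by one
// GEMM. Batch norm operates per channel row across all columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

struct ConvDef {
  std::string name;  // parameter prefix, e.g. "conv0", "s1a"
  int cin, cout, k, stride, pad, hin, win, hout, wout;
};

struct Topo {
  std::vector<ConvDef> convs;  // conv0, s{i}a, s{i}b, s{i}p ...
  int n_stages, n_classes, h0, w0;
};

static int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static Topo make_topo(const List& arch) {
  Topo t;
  IntegerVector widths = arch["widths"];  // stem, stage1..3
  t.n_classes = as<int>(arch["n_classes"]);
  t.h0 = as<int>(arch["h"]);
  t.w0 = as<int>(arch["w"]);
  t.n_stages = widths.size() - 1;
  int h = t.h0, w = t.w0, c = 1;
  ConvDef stem{"conv0", c, widths[0], 3, 1, 1, h, w, h, w};
  t.convs.push_back(stem);
  c = widths[0];
  for (int s = 1; s <= t.n_stages; ++s) {
    int co = widths[s];
    int ho = out_dim(h, 3, 2, 1), wo = out_dim(w, 3, 2, 1);
    std::string p = "s" + std::to_string(s);
    t.convs.push_back({p + "a", c, co, 3, 2, 1, h, w, ho, wo});
    t.convs.push_back({p + "b", co, co, 3, 1, 1, ho, wo, ho, wo});
    t.convs.push_back({p + "p", c, co, 1, 2, 0, h, w, ho, wo});
    c = co;
    h = ho;
    w = wo;
  }
  return t;
}

static void im2col(const mat& A, const ConvDef& d, int B, mat& cols) {
  const int HW_in = d.hin * d.win, HoWo = d.hout * d.wout, kk = d.k * d.k;
  cols.zeros(d.cin * kk, HoWo * B);
  for (int b = 0; b < B; ++b) {
    const int in_off = b * HW_in, out_off = b * HoWo;
    for (int wo = 0; wo < d.wout; ++wo) {
      for (int ho = 0; ho < d.hout; ++ho) {
        const int col = out_off + wo * d.hout + ho;
        for (int kw = 0; kw < d.k; ++kw) {
          const int w_in = wo * d.stride + kw - d.pad;
          if (w_in < 0 || w_in >= d.win) continue;
          for (int kh = 0; kh < d.k; ++kh) {
            const int h_in = ho * d.stride + kh - d.pad;
            if (h_in < 0 || h_in >= d.hin) continue;
            const int src = in_off + w_in * d.hin + h_in;
            for (int c = 0; c < d.cin; ++c)
              cols(c * kk + kw * d.k + kh, col) = A(c, src);
          }
        }
      }
    }
  }
}

static void col2im(const mat& cols, const ConvDef& d, int B, mat& dA) {
  const int HW_in = d.hin * d.win, HoWo = d.hout * d.wout, kk = d.k * d.k;
  dA.zeros(d.cin, HW_in * B);
  for (int b = 0; b < B; ++b) {
    const int in_off = b * HW_in, out_off = b * HoWo;
    for (int wo = 0; wo < d.wout; ++wo) {
      for (int ho = 0; ho < d.hout; ++ho) {
        const int col = out_off + wo * d.hout + ho;
        for (int kw = 0; kw < d.k; ++kw) {
          const int w_in = wo * d.stride + kw - d.pad;
          if (w_in < 0 || w_in >= d.win) continue;
          for (int kh = 0; kh < d.k; ++kh) {
            const int h_in = ho * d.stride + kh - d.pad;
            if (h_in < 0 || h_in >= d.hin) continue;
            const int dst = in_off + w_in * d.hin + h_in;
            for (int c = 0; c < d.cin; ++c)
              dA(c, dst) += cols(c * kk + kw * d.k + kh, col);
          }
        }
      }
    }
  }
}

static const double BN_EPS = 1e-5;

// batch-norm forward over rows; returns normalized activations, caches
// xhat and inverse stddev for backward
struct BnCache {
  mat xhat;
  vec invstd, mean, var;
};

static mat bn_forward_train(const mat& x, const vec& g, const vec& b,
                            BnCache& cache) {
  const int C = x.n_rows;
  cache.mean = arma::mean(x, 1);
  cache.var = arma::var(x, 1 /*population*/, 1);
  cache.invstd = 1.0 / arma::sqrt(cache.var + BN_EPS);
  cache.xhat = x;
  cache.xhat.each_col() -= cache.mean;
  cache.xhat.each_col() %= cache.invstd;
  mat y = cache.xhat;
  for (int c = 0; c < C; ++c) y.row(c) = y.row(c) * g(c) + b(c);
  return y;
}

static mat bn_forward_infer(const mat& x, const vec& g, const vec& b,
                            const vec& rmean, const vec& rvar) {
  mat y = x;
  for (arma::uword c = 0; c < x.n_rows; ++c) {
    double inv = 1.0 / std::sqrt(rvar(c) + BN_EPS);
    y.row(c) = (x.row(c) - rmean(c)) * inv * g(c) + b(c);
  }
  return y;
}

static mat bn_backward(const mat& dy, const vec& g, const BnCache& cache,
                       vec& dg, vec& db) {
  const int C = dy.n_rows;
  const double N = dy.n_cols;
  dg.set_size(C);
  db.set_size(C);
  mat dx(dy.n_rows, dy.n_cols);
  for (int c = 0; c < C; ++c) {
    arma::rowvec dyr = dy.row(c);
    arma::rowvec xh = cache.xhat.row(c);
    dg(c) = arma::dot(dyr, xh);
    db(c) = arma::accu(dyr);
    arma::rowvec dxhat = dyr * g(c);
    double s1 = arma::accu(dxhat), s2 = arma::dot(dxhat, xh);
    dx.row(c) = cache.invstd(c) / N * (N * dxhat - s1 - xh * s2);
  }
  return dx;
}

// fake-quantize activations in place: q = clamp(round(x/s)+zp), x = s*(q-zp)
static void fake_quant(mat& x, double s, int zp) {
  if (s <= 0) return;
  x = arma::clamp(arma::round(x / s) + zp, -128.0, 127.0);
  x = (x - zp) * s;
}

static mat input_to_mat(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  mat A(1, H * W * B);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) A(0, b * H * W + w * H + h) = x(h, w, b);
  return A;
}

static mat gap(const mat& A, int HW, int B) {
  mat pooled(A.n_rows, B);
  for (int b = 0; b < B; ++b)
    pooled.col(b) = arma::mean(A.cols(b * HW, (b + 1) * HW - 1), 1);
  return pooled;
}

static mat softmax_cols(const mat& logits) {
  mat p = logits;
  for (arma::uword j = 0; j < p.n_cols; ++j) {
    vec c = p.col(j) - p.col(j).max();
    c = arma::exp(c);
    p.col(j) = c / arma::accu(c);
  }
  return p;
}

// [[Rcpp::export]]
List cnn_fwd_bwd(List params, arma::cube x, arma::ivec y, List arch) {
  Topo t = make_topo(arch);
  const int B = x.n_slices;
  mat A = input_to_mat(x);

  std::map<std::string, mat> acts, cols_cache, preacts;
  std::map<std::string, BnCache> bns;
  std::map<std::string, arma::umat> relu_mask;

  auto conv_fwd = [&](const ConvDef& d, const mat& in) {
    mat cols;
    im2col(in, d, B, cols);
    cols_cache[d.name] = cols;
    mat W = as<mat>(params[d.name + "_w"]);
    return mat(W * cols);
  };
  auto bn_fwd = [&](const std::string& nm, const mat& z) {
    return bn_forward_train(z, as<vec>(params[nm + "_g"]),
                            as<vec>(params[nm + "_b"]), bns[nm]);
  };

  // stem
  const ConvDef& c0 = t.convs[0];
  acts["in"] = A;
  mat h = bn_fwd("bn0", conv_fwd(c0, A));
  relu_mask["bn0"] = h > 0;
  h = h % arma::conv_to<mat>::from(relu_mask["bn0"]);
  acts["stem"] = h;

  // stages
  std::vector<std::string> stage_in_name{"stem"};
  for (int s = 1; s <= t.n_stages; ++s) {
    const ConvDef& da = t.convs[1 + (s - 1) * 3];
    const ConvDef& db_ = t.convs[2 + (s - 1) * 3];
    const ConvDef& dp = t.convs[3 + (s - 1) * 3];
    std::string p = "s" + std::to_string(s);
    mat in = h;
    acts[p + "_in"] = in;
    mat za = bn_fwd(p + "a", conv_fwd(da, in));
    relu_mask[p + "a"] = za > 0;
    za = za % arma::conv_to<mat>::from(relu_mask[p + "a"]);
    acts[p + "_mid"] = za;
    mat zb = bn_fwd(p + "b", conv_fwd(db_, za));
    mat zp = bn_fwd(p + "p", conv_fwd(dp, in));
    mat sum = zb + zp;
    relu_mask[p] = sum > 0;
    h = sum % arma::conv_to<mat>::from(relu_mask[p]);
    acts[p + "_out"] = h;
  }

  const ConvDef& last = t.convs[1 + (t.n_stages - 1) * 3];
  const int HW_last = last.hout * last.wout;
  mat pooled = gap(h, HW_last, B);
  mat fc_w = as<mat>(params["fc_w"]);
  vec fc_b = as<vec>(params["fc_b"]);
  mat logits = fc_w * pooled;
  logits.each_col() += fc_b;
  mat probs = softmax_cols(logits);

  double loss = 0;
  int correct = 0;
  mat dlogits = probs;
  for (int b = 0; b < B; ++b) {
    int cls = y(b);
    loss -= std::log(std::max(probs(cls, b), 1e-12));
    dlogits(cls, b) -= 1.0;
    if ((int)probs.col(b).index_max() == cls) ++correct;
  }
  loss /= B;
  dlogits /= B;

  List grads;
  grads["fc_w"] = mat(dlogits * pooled.t());
  grads["fc_b"] = vec(arma::sum(dlogits, 1));

  mat dpooled = fc_w.t() * dlogits;
  mat dh(h.n_rows, h.n_cols);
  for (int b = 0; b < B; ++b)
    dh.cols(b * HW_last, (b + 1) * HW_last - 1) =
        arma::repmat(dpooled.col(b) / HW_last, 1, HW_last);

  auto conv_bwd = [&](const ConvDef& d, const mat& dz, mat& dW, mat& din) {
    dW = dz * cols_cache[d.name].t();
    mat dcols = as<mat>(params[d.name + "_w"]).t() * dz;
    col2im(dcols, d, B, din);
  };
  auto bn_bwd = [&](const std::string& nm, const mat& dz) {
    vec dg, dbv;
    mat dx = bn_backward(dz, as<vec>(params[nm + "_g"]), bns[nm], dg, dbv);
    grads[nm + "_g"] = dg;
    grads[nm + "_b"] = dbv;
    return dx;
  };

  for (int s = t.n_stages; s >= 1; --s) {
    const ConvDef& da = t.convs[1 + (s - 1) * 3];
    const ConvDef& db_ = t.convs[2 + (s - 1) * 3];
    const ConvDef& dp = t.convs[3 + (s - 1) * 3];
    std::string p = "s" + std::to_string(s);
    mat dsum = dh % arma::conv_to<mat>::from(relu_mask[p]);
    // branch b: bn_b <- conv_b <- relu(a) ; branch p: bn_p <- conv_p <- in
    mat dzb = bn_bwd(p + "b", dsum);
    mat dWb, dmid;
    conv_bwd(db_, dzb, dWb, dmid);
    grads[db_.name + "_w"] = dWb;
    mat dzp = bn_bwd(p + "p", dsum);
    mat dWp, din_p;
    conv_bwd(dp, dzp, dWp, din_p);
    grads[dp.name + "_w"] = dWp;

    dmid = dmid % arma::conv_to<mat>::from(relu_mask[p + "a"]);
    mat dza = bn_bwd(p + "a", dmid);
    mat dWa, din_a;
    conv_bwd(da, dza, dWa, din_a);
    grads[da.name + "_w"] = dWa;
    dh = din_a + din_p;
  }

  mat dstem = dh % arma::conv_to<mat>::from(relu_mask["bn0"]);
  mat dz0 = bn_bwd("bn0", dstem);
  mat dW0, din0;
  conv_bwd(c0, dz0, dW0, din0);
  grads["conv0_w"] = dW0;

  List bn_mean, bn_var;
  for (auto& kv : bns) {
    bn_mean[kv.first] = kv.second.mean;
    bn_var[kv.first] = kv.second.var;
  }
  return List::create(_["loss"] = loss, _["acc"] = (double)correct / B,
                      _["grads"] = grads, _["bn_mean"] = bn_mean,
                      _["bn_var"] = bn_var);
}

// [[Rcpp::export]]
arma::mat cnn_infer(List params, List running, arma::cube x, List arch) {
  Topo t = make_topo(arch);
  const int B = x.n_slices;
  mat h = input_to_mat(x);

  auto conv = [&](const ConvDef& d, const mat& in) {
    mat cols;
    im2col(in, d, B, cols);
    return mat(as<mat>(params[d.name + "_w"]) * cols);
  };
  auto bn = [&](const std::string& nm, const mat& z) {
    return bn_forward_infer(z, as<vec>(params[nm + "_g"]),
                            as<vec>(params[nm + "_b"]),
                            as<vec>(running[nm + "_m"]),
                            as<vec>(running[nm + "_v"]));
  };

  h = bn("bn0", conv(t.convs[0], h));
  h = arma::clamp(h, 0.0, arma::datum::inf);
  for (int s = 1; s <= t.n_stages; ++s) {
    std::string p = "s" + std::to_string(s);
    mat in = h;
    mat za = bn(p + "a", conv(t.convs[1 + (s - 1) * 3], in));
    za = arma::clamp(za, 0.0, arma::datum::inf);
    mat zb = bn(p + "b", conv(t.convs[2 + (s - 1) * 3], za));
    mat zp = bn(p + "p", conv(t.convs[3 + (s - 1) * 3], in));
    h = arma::clamp(zb + zp, 0.0, arma::datum::inf);
  }
  const ConvDef& last = t.convs[1 + (t.n_stages - 1) * 3];
  mat pooled = gap(h, last.hout * last.wout, B);
  mat logits = as<mat>(params["fc_w"]) * pooled;
  logits.each_col() += as<vec>(params["fc_b"]);
  return softmax_cols(logits).t();  // B x K
}

// Inference through a BN-folded network (conv layers carry per-channel
// biases). Optionally fake-quantizes activations at the standard points
// (input, each ReLU output, pooled vector) with per-point affine int8
// parameters, or records observed min/max ranges for calibration.
// [[Rcpp::export]]
List cnn_infer_folded(List params, arma::cube x, List arch, bool record,
                      Nullable<NumericVector> act_scale_,
                      Nullable<IntegerVector> act_zp_) {
  Topo t = make_topo(arch);
  const int B = x.n_slices;
  bool do_quant = act_scale_.isNotNull();
  NumericVector act_scale = do_quant ? NumericVector(act_scale_)
                                     : NumericVector(0);
  IntegerVector act_zp = do_quant ? IntegerVector(act_zp_)
                                  : IntegerVector(0);
  std::vector<double> mins, maxs;
  int qi = 0;
  auto qpoint = [&](mat& h) {
    if (record) {
      mins.push_back(h.min());
      maxs.push_back(h.max());
    }
    if (do_quant) fake_quant(h, act_scale[qi], act_zp[qi]);
    ++qi;
  };

  auto conv = [&](const ConvDef& d, const mat& in) {
    mat cols;
    im2col(in, d, B, cols);
    mat z = as<mat>(params[d.name + "_w"]) * cols;
    vec bias = as<vec>(params[d.name + "_bias"]);
    z.each_col() += bias;
    return z;
  };

  mat h = input_to_mat(x);
  qpoint(h);
  h = arma::clamp(conv(t.convs[0], h), 0.0, arma::datum::inf);
  qpoint(h);
  for (int s = 1; s <= t.n_stages; ++s) {
    mat in = h;
    mat za = arma::clamp(conv(t.convs[1 + (s - 1) * 3], in), 0.0,
                         arma::datum::inf);
    mat zb = conv(t.convs[2 + (s - 1) * 3], za);
    mat zp = conv(t.convs[3 + (s - 1) * 3], in);
    h = arma::clamp(zb + zp, 0.0, arma::datum::inf);
    qpoint(h);
  }
  const ConvDef& last = t.convs[1 + (t.n_stages - 1) * 3];
  mat pooled = gap(h, last.hout * last.wout, B);
  qpoint(pooled);
  mat logits = as<mat>(params["fc_w"]) * pooled;
  logits.each_col() += as<vec>(params["fc_b"]);
  mat probs = softmax_cols(logits).t();
  return List::create(_["probs"] = probs,
                      _["mins"] = NumericVector(mins.begin(), mins.end()),
                      _["maxs"] = NumericVector(maxs.begin(), maxs.end()));
}
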