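// Compact CNN engine for B-scan segmentation: two fixed architectures
// (4-level encoder-decoder with skip connections; constant-resolution
// multi-dilation network), im2col convolutions, sigmoid/BCE or soft-Dice
// loss, and Adam. Weights use a fixed-gain parameterization: the effective
// weight is GAIN * stored parameter, so Adam steps of the configured
// learning rate produce effective updates of lr * GAIN. Deterministic for a
// fixed seed (own mt19937 stream; no global RNG state).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static const double GAIN = 128.0;

struct ConvSpec { int k; int d; int cin; int cout; };

struct Net {
  std::string arch;
  std::vector<ConvSpec> spec;
  std::vector<mat> W;  // cout x (k*k*cin), stored (pre-gain) scale
  std::vector<vec> b;
};

static std::vector<ConvSpec> arch_spec(const std::string& arch, int c) {
  std::vector<ConvSpec> s;
  if (arch == "encoder_decoder") {
    // 4 resolution levels: enough receptive field to see a whole A-scan's
    // retinal band stack at the bottleneck
    int c1 = c, c2 = 2 * c, c3 = 4 * c, c4 = 8 * c;
    s.push_back({3, 1, 1, c1});        // enc1 (full res)
    s.push_back({3, 1, c1, c2});       // enc2 (/2)
    s.push_back({3, 1, c2, c3});       // enc3 (/4)
    s.push_back({3, 1, c3, c4});       // bottleneck (/8)
    s.push_back({3, 1, c4 + c3, c3});  // dec3
    s.push_back({3, 1, c3 + c2, c2});  // dec2
    s.push_back({3, 1, c2 + c1, c1});  // dec1
    s.push_back({1, 1, c1, 3});        // head
  } else if (arch == "dilated") {
    // two-conv stem, then parallel dilation branches 1/2/4/8 at constant
    // resolution, fused and projected
    s.push_back({3, 1, 1, c});         // stem1
    s.push_back({3, 2, c, c});         // stem2
    s.push_back({3, 1, c, c});         // branch d=1
    s.push_back({3, 2, c, c});         // branch d=2
    s.push_back({3, 4, c, c});         // branch d=4
    s.push_back({3, 8, c, c});         // branch d=8
    s.push_back({3, 1, 4 * c, 2 * c}); // fuse
    s.push_back({1, 1, 2 * c, 3});     // head
  } else {
    Rcpp::stop("unknown architecture '" + arch + "'");
  }
  return s;
}

// ---------------------------------------------------------------- im2col
// cols layout: (H*W) x (k*k*cin); spatial position (i,j) flattens to j*H+i
// (column-major), matching arma::reshape/vectorise.
static mat im2col(const cube& in, int k, int d) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int kk = k * k, off = (k - 1) / 2;
  mat out(H * W, kk * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& ch = in.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      const int dr = (ki - off) * d;
      const int i0 = std::max(0, -dr), i1 = std::min(H - 1, H - 1 - dr);
      if (i0 > i1) continue;
      for (int kj = 0; kj < k; ++kj) {
        const int dc = (kj - off) * d;
        const int col = c * kk + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dc;
          if (sj < 0 || sj >= W) continue;
          out.col(col).subvec(j * H + i0, j * H + i1) =
            ch.col(sj).subvec(i0 + dr, i1 + dr);
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& dcols, int k, int d, int H, int W, int C) {
  const int kk = k * k, off = (k - 1) / 2;
  cube din(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& ch = din.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      const int dr = (ki - off) * d;
      const int i0 = std::max(0, -dr), i1 = std::min(H - 1, H - 1 - dr);
      if (i0 > i1) continue;
      for (int kj = 0; kj < k; ++kj) {
        const int dc = (kj - off) * d;
        const int col = c * kk + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dc;
          if (sj < 0 || sj >= W) continue;
          ch.col(sj).subvec(i0 + dr, i1 + dr) +=
            dcols.col(col).subvec(j * H + i0, j * H + i1);
        }
      }
    }
  }
  return din;
}

struct ConvCache { mat cols; int H = 0, W = 0; };

static cube conv_fwd(const Net& net, int li, const cube& in, ConvCache& cc) {
  const ConvSpec& s = net.spec[li];
  cc.H = in.n_rows; cc.W = in.n_cols;
  cc.cols = im2col(in, s.k, s.d);
  mat out = cc.cols * net.W[li].t() * GAIN;
  out.each_row() += (GAIN * net.b[li]).t();
  cube o(cc.H, cc.W, s.cout);
  for (int c = 0; c < s.cout; ++c) {
    o.slice(c) = reshape(out.col(c), cc.H, cc.W);
  }
  return o;
}

static cube conv_bwd(const Net& net, int li, const cube& dout,
                     const ConvCache& cc, mat& dW, vec& db, bool need_din) {
  const ConvSpec& s = net.spec[li];
  const int HW = cc.H * cc.W;
  mat dOut(HW, s.cout);
  for (int c = 0; c < s.cout; ++c) dOut.col(c) = vectorise(dout.slice(c));
  dW += GAIN * (dOut.t() * cc.cols);
  db += GAIN * sum(dOut, 0).t();
  if (!need_din) return cube();
  mat dcols = dOut * (GAIN * net.W[li]);
  return col2im(dcols, s.k, s.d, cc.H, cc.W, s.cin);
}

static cube relu(const cube& x) { return clamp(x, 0.0, datum::inf); }
static cube relu_bwd(const cube& dout, const cube& pre) {
  cube d = dout;
  d.elem(find(pre <= 0)).zeros();
  return d;
}

static cube maxpool2(const cube& in, ucube& idx) {
  const int H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  cube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double best = in(2 * i, 2 * j, c);
        int bi = 0;
        const int di[4] = {0, 1, 0, 1}, dj[4] = {0, 0, 1, 1};
        for (int t = 1; t < 4; ++t) {
          double v = in(2 * i + di[t], 2 * j + dj[t], c);
          if (v > best) { best = v; bi = t; }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return out;
}

static cube maxpool2_bwd(const cube& dout, const ucube& idx, int H, int W) {
  const int C = dout.n_slices;
  cube din(H, W, C, fill::zeros);
  const int di[4] = {0, 1, 0, 1}, dj[4] = {0, 0, 1, 1};
  for (int c = 0; c < C; ++c) {
    for (unsigned j = 0; j < dout.n_cols; ++j) {
      for (unsigned i = 0; i < dout.n_rows; ++i) {
        const int t = idx(i, j, c);
        din(2 * i + di[t], 2 * j + dj[t], c) += dout(i, j, c);
      }
    }
  }
  return din;
}

static cube upsample2(const cube& in) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = in(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return out;
}

static cube upsample2_bwd(const cube& dout) {
  const int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  cube din(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        din(i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                       dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return din;
}

static cube concat_channels(const cube& a, const cube& b) {
  cube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  out.slices(0, a.n_slices - 1) = a;
  out.slices(a.n_slices, out.n_slices - 1) = b;
  return out;
}

// ------------------------------------------------------------- forward
struct FwdCache {
  std::vector<ConvCache> cc;
  std::vector<cube> pre;   // pre-activation of each conv (for ReLU backward)
  ucube p1idx, p2idx, p3idx;
  cube a0, a1, a2;         // skip activations (encoder-decoder)
  int H0 = 0, W0 = 0, H1 = 0, W1 = 0, H2 = 0, W2 = 0;
};

static cube net_forward(const Net& net, const cube& x, FwdCache& f) {
  const int L = net.spec.size();
  f.cc.assign(L, ConvCache());
  f.pre.assign(L, cube());
  if (net.arch == "encoder_decoder") {
    f.pre[0] = conv_fwd(net, 0, x, f.cc[0]);
    f.a0 = relu(f.pre[0]);
    f.H0 = f.a0.n_rows; f.W0 = f.a0.n_cols;
    cube p1 = maxpool2(f.a0, f.p1idx);
    f.pre[1] = conv_fwd(net, 1, p1, f.cc[1]);
    f.a1 = relu(f.pre[1]);
    f.H1 = f.a1.n_rows; f.W1 = f.a1.n_cols;
    cube p2 = maxpool2(f.a1, f.p2idx);
    f.pre[2] = conv_fwd(net, 2, p2, f.cc[2]);
    f.a2 = relu(f.pre[2]);
    f.H2 = f.a2.n_rows; f.W2 = f.a2.n_cols;
    cube p3 = maxpool2(f.a2, f.p3idx);
    f.pre[3] = conv_fwd(net, 3, p3, f.cc[3]);
    cube bott = relu(f.pre[3]);
    cube u3 = concat_channels(upsample2(bott), f.a2);
    f.pre[4] = conv_fwd(net, 4, u3, f.cc[4]);
    cube d3 = relu(f.pre[4]);
    cube u2 = concat_channels(upsample2(d3), f.a1);
    f.pre[5] = conv_fwd(net, 5, u2, f.cc[5]);
    cube d2 = relu(f.pre[5]);
    cube u1 = concat_channels(upsample2(d2), f.a0);
    f.pre[6] = conv_fwd(net, 6, u1, f.cc[6]);
    cube d1 = relu(f.pre[6]);
    f.pre[7] = conv_fwd(net, 7, d1, f.cc[7]);
    return f.pre[7];
  }
  // dilated: two-conv stem, four parallel dilation branches, fuse, project
  f.pre[0] = conv_fwd(net, 0, x, f.cc[0]);
  cube stem1 = relu(f.pre[0]);
  f.pre[1] = conv_fwd(net, 1, stem1, f.cc[1]);
  cube stem = relu(f.pre[1]);
  f.pre[2] = conv_fwd(net, 2, stem, f.cc[2]);
  f.pre[3] = conv_fwd(net, 3, stem, f.cc[3]);
  f.pre[4] = conv_fwd(net, 4, stem, f.cc[4]);
  f.pre[5] = conv_fwd(net, 5, stem, f.cc[5]);
  cube cat = concat_channels(concat_channels(relu(f.pre[2]), relu(f.pre[3])),
                             concat_channels(relu(f.pre[4]), relu(f.pre[5])));
  f.pre[6] = conv_fwd(net, 6, cat, f.cc[6]);
  cube fuse = relu(f.pre[6]);
  f.pre[7] = conv_fwd(net, 7, fuse, f.cc[7]);
  return f.pre[7];
}

static void net_backward(const Net& net, const FwdCache& f, const cube& dlogits,
                         std::vector<mat>& dW, std::vector<vec>& db) {
  if (net.arch == "encoder_decoder") {
    cube dhead = conv_bwd(net, 7, dlogits, f.cc[7], dW[7], db[7], true);
    cube dd1 = relu_bwd(dhead, f.pre[6]);
    cube du1 = conv_bwd(net, 6, dd1, f.cc[6], dW[6], db[6], true);
    const int c1 = net.spec[0].cout, c2 = net.spec[1].cout,
              c3 = net.spec[2].cout, c4 = net.spec[3].cout;
    cube dup1 = du1.slices(0, c2 - 1);
    cube da0_skip = du1.slices(c2, c2 + c1 - 1);
    cube dd2 = relu_bwd(upsample2_bwd(dup1), f.pre[5]);
    cube du2 = conv_bwd(net, 5, dd2, f.cc[5], dW[5], db[5], true);
    cube dup2 = du2.slices(0, c3 - 1);
    cube da1_skip = du2.slices(c3, c3 + c2 - 1);
    cube dd3 = relu_bwd(upsample2_bwd(dup2), f.pre[4]);
    cube du3 = conv_bwd(net, 4, dd3, f.cc[4], dW[4], db[4], true);
    cube dup3 = du3.slices(0, c4 - 1);
    cube da2_skip = du3.slices(c4, c4 + c3 - 1);
    cube dbott = relu_bwd(upsample2_bwd(dup3), f.pre[3]);
    cube dp3 = conv_bwd(net, 3, dbott, f.cc[3], dW[3], db[3], true);
    cube da2 = maxpool2_bwd(dp3, f.p3idx, f.H2, f.W2) + da2_skip;
    cube dpre2 = relu_bwd(da2, f.pre[2]);
    cube dp2 = conv_bwd(net, 2, dpre2, f.cc[2], dW[2], db[2], true);
    cube da1 = maxpool2_bwd(dp2, f.p2idx, f.H1, f.W1) + da1_skip;
    cube dpre1 = relu_bwd(da1, f.pre[1]);
    cube dp1 = conv_bwd(net, 1, dpre1, f.cc[1], dW[1], db[1], true);
    cube da0 = maxpool2_bwd(dp1, f.p1idx, f.H0, f.W0) + da0_skip;
    cube dpre0 = relu_bwd(da0, f.pre[0]);
    conv_bwd(net, 0, dpre0, f.cc[0], dW[0], db[0], false);
    return;
  }
  cube dhead = conv_bwd(net, 7, dlogits, f.cc[7], dW[7], db[7], true);
  cube dfuse_in = relu_bwd(dhead, f.pre[6]);
  cube dcat = conv_bwd(net, 6, dfuse_in, f.cc[6], dW[6], db[6], true);
  const int c = net.spec[2].cout;
  cube dstem(f.pre[1].n_rows, f.pre[1].n_cols, net.spec[1].cout, fill::zeros);
  for (int br = 0; br < 4; ++br) {
    cube dbr = relu_bwd(dcat.slices(br * c, (br + 1) * c - 1), f.pre[2 + br]);
    dstem += conv_bwd(net, 2 + br, dbr, f.cc[2 + br], dW[2 + br], db[2 + br], true);
  }
  cube dpre1 = relu_bwd(dstem, f.pre[1]);
  cube dstem1 = conv_bwd(net, 1, dpre1, f.cc[1], dW[1], db[1], true);
  cube dpre0 = relu_bwd(dstem1, f.pre[0]);
  conv_bwd(net, 0, dpre0, f.cc[0], dW[0], db[0], false);
}

// ---------------------------------------------------------------- losses
static double bce_loss_grad(const cube& z, const cube& y, cube& dz) {
  // numerically stable BCE with logits; mean over pixels and channels
  const double n = z.n_elem;
  cube zpos = clamp(z, 0.0, datum::inf);
  cube l = zpos - z % y + log(1.0 + exp(-abs(z)));
  dz = (1.0 / (1.0 + exp(-z)) - y) / n;
  return accu(l) / n;
}

static double dice_loss_grad(const cube& z, const cube& y, cube& dz) {
  // soft Dice per channel, averaged; smoothing 1 guards empty channels
  dz.set_size(z.n_rows, z.n_cols, z.n_slices);
  double loss = 0.0;
  const int C = z.n_slices;
  for (int c = 0; c < C; ++c) {
    mat p = 1.0 / (1.0 + exp(-z.slice(c)));
    const mat& yc = y.slice(c);
    const double num = 2.0 * accu(p % yc) + 1.0;
    const double den = accu(p) + accu(yc) + 1.0;
    loss += 1.0 - num / den;
    mat dp = -(2.0 * yc * den - num) / (den * den);
    dz.slice(c) = (dp % p % (1.0 - p)) / C;
  }
  return loss / C;
}

// ----------------------------------------------------------- param glue
static Net net_from_params(const std::string& arch, const List& params) {
  Net net;
  net.arch = arch;
  const List Ws = params["W"], bs = params["b"];
  const int base = Rcpp::as<int>(params["base_channels"]);
  net.spec = arch_spec(arch, base);
  for (size_t i = 0; i < net.spec.size(); ++i) {
    net.W.push_back(Rcpp::as<mat>(Ws[i]));
    net.b.push_back(Rcpp::as<vec>(bs[i]));
    if ((int)net.W[i].n_rows != net.spec[i].cout ||
        (int)net.W[i].n_cols != net.spec[i].k * net.spec[i].k * net.spec[i].cin) {
      Rcpp::stop("parameter shapes do not match architecture");
    }
  }
  return net;
}

static List params_to_list(const Net& net, int base) {
  const int L = net.spec.size();
  List Ws(L), bs(L);
  for (int i = 0; i < L; ++i) { Ws[i] = net.W[i]; bs[i] = net.b[i]; }
  return List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs,
                      Rcpp::Named("base_channels") = base,
                      Rcpp::Named("arch") = net.arch);
}

// [[Rcpp::export]]
List nn_init_cpp(std::string arch, int base_channels, int seed) {
  Net net;
  net.arch = arch;
  net.spec = arch_spec(arch, base_channels);
  std::mt19937 rng(static_cast<uint32_t>(seed) ^ 0x9e3779b9u);
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (const ConvSpec& s : net.spec) {
    const int fan_in = s.k * s.k * s.cin;
    const double sd_eff = std::sqrt(2.0 / fan_in);  // He init on effective scale
    mat W(s.cout, fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = gauss(rng) * sd_eff / GAIN;
    net.W.push_back(W);
    net.b.push_back(vec(s.cout, fill::zeros));
  }
  return params_to_list(net, base_channels);
}

// [[Rcpp::export]]
arma::cube nn_forward_cpp(std::string arch, List params, arma::mat x) {
  Net net = net_from_params(arch, params);
  cube xin(x.n_rows, x.n_cols, 1);
  xin.slice(0) = x;
  FwdCache f;
  return net_forward(net, xin, f);
}

// Seeded train-time intensity augmentation: multiplicative speckle with a
// random contrast, gamma jitter and brightness/scale jitter. Emulates the
// appearance variability across devices without touching the labels.
static mat sep_gauss_blur(const mat& x, double sigma) {
  const int r = std::max(1, (int)std::ceil(2.0 * sigma));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= accu(k);
  const int H = x.n_rows, W = x.n_cols;
  mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(std::max(i + t, 0), H - 1);
        s += k(t + r) * x(ii, j);
      }
      tmp(i, j) = s;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(std::max(j + t, 0), W - 1);
        s += k(t + r) * tmp(i, jj);
      }
      out(i, j) = s;
    }
  }
  return out;
}

static mat augment_bscan(const mat& x, std::mt19937& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  mat out = x;
  const double c = 0.7 * U(rng);  // speckle contrast
  if (c > 0.02) {
    const double k = 1.0 / (c * c);
    std::gamma_distribution<double> G(k, 1.0 / k);
    for (uword i = 0; i < out.n_elem; ++i) out(i) *= G(rng);
  }
  const double blur = 1.3 * U(rng);  // emulates interpolation smoothing
  if (blur > 0.15) out = sep_gauss_blur(out, blur);
  const double g = 0.65 + 0.75 * U(rng);  // gamma exponent
  const double s = 0.8 + 0.4 * U(rng);    // scale
  const double b = -0.05 + 0.1 * U(rng);  // brightness shift
  out = clamp(out, 0.0, 1.0);
  out = s * pow(out, g) + b;
  return clamp(out, 0.0, 1.0);
}

// [[Rcpp::export]]
List nn_train_cpp(std::string arch, List params_in, arma::cube X, arma::cube Y,
                  int epochs, double lr, int batch_size, int seed,
                  std::string loss, bool augment) {
  Net net = net_from_params(arch, params_in);
  const int base = Rcpp::as<int>(params_in["base_channels"]);
  const int N = X.n_slices;
  if ((int)Y.n_slices != 3 * N) Rcpp::stop("labels must have 3 channels per B-scan");
  if (batch_size < 1) Rcpp::stop("batch_size must be >= 1");
  const bool use_dice = (loss == "dice");

  const int L = net.spec.size();
  std::vector<mat> mW(L), vW(L), dW(L);
  std::vector<vec> mb(L), vb(L), db(L);
  for (int i = 0; i < L; ++i) {
    mW[i].zeros(size(net.W[i])); vW[i].zeros(size(net.W[i]));
    mb[i].zeros(net.b[i].n_elem); vb[i].zeros(net.b[i].n_elem);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  vec epoch_loss(epochs, fill::zeros);
  std::mt19937 rng(static_cast<uint32_t>(seed) ^ 0x51f15eedu);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with explicit draws (stdlib-independent determinism)
    for (int i = N - 1; i > 0; --i) {
      const int j = static_cast<int>(rng() % static_cast<uint32_t>(i + 1));
      std::swap(order[i], order[j]);
    }
    double ep_sum = 0.0;
    int in_batch = 0;
    for (int i = 0; i < L; ++i) { dW[i].zeros(size(net.W[i])); db[i].zeros(net.b[i].n_elem); }
    for (int n = 0; n < N; ++n) {
      const int s = order[n];
      cube xin(X.n_rows, X.n_cols, 1);
      xin.slice(0) = augment ? augment_bscan(X.slice(s), rng) : X.slice(s);
      cube y(X.n_rows, X.n_cols, 3);
      for (int c = 0; c < 3; ++c) y.slice(c) = Y.slice(3 * s + c);
      if (augment && (rng() & 1u)) {  // left-right anatomical flip
        xin.slice(0) = fliplr(xin.slice(0));
        for (int c = 0; c < 3; ++c) y.slice(c) = fliplr(y.slice(c));
      }
      FwdCache f;
      cube z = net_forward(net, xin, f);
      cube dz;
      const double l = use_dice ? dice_loss_grad(z, y, dz) : bce_loss_grad(z, y, dz);
      ep_sum += l;
      net_backward(net, f, dz, dW, db);
      ++in_batch;
      if (in_batch == batch_size || n == N - 1) {
        ++t;
        const double corr = std::sqrt(1.0 - std::pow(b2, t)) / (1.0 - std::pow(b1, t));
        for (int i = 0; i < L; ++i) {
          mat gW = dW[i] / in_batch;
          vec gb = db[i] / in_batch;
          mW[i] = b1 * mW[i] + (1 - b1) * gW;
          vW[i] = b2 * vW[i] + (1 - b2) * square(gW);
          net.W[i] -= lr * corr * mW[i] / (sqrt(vW[i]) + eps);
          mb[i] = b1 * mb[i] + (1 - b1) * gb;
          vb[i] = b2 * vb[i] + (1 - b2) * square(gb);
          net.b[i] -= lr * corr * mb[i] / (sqrt(vb[i]) + eps);
          dW[i].zeros(); db[i].zeros();
        }
        in_batch = 0;
      }
    }
    epoch_loss(ep) = ep_sum / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Rcpp::Named("params") = params_to_list(net, base),
                      Rcpp::Named("epoch_loss") = epoch_loss,
                      Rcpp::Named("n_steps") = (double)t);
}
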