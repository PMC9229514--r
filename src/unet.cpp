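// 3D U-Net computational core: forward pass, hand-derived reverse-mode
// backward pass, and the class-weighted generalized Dice loss.
//
// Layout conventions
//   * Activations are Mat<eT>(C, Nvox * B): channels in rows, one column per
//     voxel, batch items contiguous (column = b * Nvox + v, v = x + H*(y + W*z)).
//   * Conv weights are Mat<eT>(Cout, k^3 * Cin), column q = o * Cin + cin with
//     kernel offset o = kx + k*ky + k^2*kz (offsets -1..1 for k = 3).
//   * Transposed 2x2x2 stride-2 conv weights are 8 matrices (Cout x Cin), one
//     per output sub-grid offset o = rx + 2*ry + 4*rz.
//   * Convolutions use stride 1 and 'same' zero padding (k = 3 or 1), realised
//     by per-z-slice im2col + GEMM so scratch memory stays bounded.
//
// The same templated code runs in float (training speed) and double
// (numerical validation against central finite differences in the tests).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <array>
#include <cstring>
#include <map>
#include <string>
#include <vector>

using namespace arma;

static const double BN_EPS = 1e-5;
static const double LOSS_SMOOTH = 1e-8;

struct LevelDims {
  int H, W, D;
  int N() const { return H * W * D; }
};

enum class OpKind { Conv, BN, Relu, Pool, TConv, Save, Concat, Softmax };

struct OpDef {
  OpKind kind;
  std::string name;  // parameter name prefix, where applicable
  int k = 3;         // conv kernel edge
  int level = 0;     // resolution level of the op's input
  int slot = -1;     // skip slot for Save/Concat
};

struct ConvDef { std::string name; int cin, cout, k; };
struct TConvDef { std::string name; int c; };
struct BNDef { std::string name; int c; };

struct NetPlan {
  int base, cin, K;
  double leaky;
  std::vector<OpDef> ops;
  std::map<std::string, ConvDef> convs;
  std::map<std::string, TConvDef> tconvs;
  std::map<std::string, BNDef> bns;
};

static NetPlan make_plan(int base, int cin, int K, double leaky) {
  NetPlan p;
  p.base = base; p.cin = cin; p.K = K; p.leaky = leaky;
  const int c = base;
  auto conv = [&](const std::string& n, int ci, int co, int k) {
    p.convs[n] = ConvDef{n, ci, co, k};
  };
  conv("en1_conv1", cin, c, 3);       conv("en1_conv2", c, 2 * c, 3);
  conv("en2_conv1", 2 * c, 2 * c, 3); conv("en2_conv2", 2 * c, 4 * c, 3);
  conv("en3_conv1", 4 * c, 4 * c, 3); conv("en3_conv2", 4 * c, 8 * c, 3);
  conv("de4_conv1", 8 * c, 8 * c, 3); conv("de4_conv2", 8 * c, 16 * c, 3);
  conv("de3_conv1", 24 * c, 8 * c, 3); conv("de3_conv2", 8 * c, 8 * c, 3);
  conv("de2_conv1", 12 * c, 4 * c, 3); conv("de2_conv2", 4 * c, 4 * c, 3);
  conv("de1_conv1", 6 * c, 2 * c, 3);  conv("de1_conv2", 2 * c, 2 * c, 3);
  conv("convlast", 2 * c, K, 1);
  p.tconvs["de4_transconv"] = TConvDef{"de4_transconv", 16 * c};
  p.tconvs["de3_transconv"] = TConvDef{"de3_transconv", 8 * c};
  p.tconvs["de2_transconv"] = TConvDef{"de2_transconv", 4 * c};
  p.bns["en1_bn1"] = BNDef{"en1_bn1", c};
  p.bns["en2_bn1"] = BNDef{"en2_bn1", 2 * c};
  p.bns["en3_bn1"] = BNDef{"en3_bn1", 4 * c};

  auto op = [&](OpKind kind, const std::string& n, int k, int lvl, int slot) {
    p.ops.push_back(OpDef{kind, n, k, lvl, slot});
  };
  for (int e = 1; e <= 3; ++e) {
    const int lvl = e - 1;
    const std::string pre = "en" + std::to_string(e);
    op(OpKind::Conv, pre + "_conv1", 3, lvl, -1);
    op(OpKind::BN, pre + "_bn1", 0, lvl, -1);
    op(OpKind::Relu, "", 0, lvl, -1);
    op(OpKind::Conv, pre + "_conv2", 3, lvl, -1);
    op(OpKind::Relu, "", 0, lvl, -1);
    op(OpKind::Save, "", 0, lvl, e - 1);
    op(OpKind::Pool, "", 0, lvl, -1);
  }
  for (int d = 4; d >= 1; --d) {
    const int lvl = d - 1;
    const std::string pre = "de" + std::to_string(d);
    op(OpKind::Conv, pre + "_conv1", 3, lvl, -1);
    op(OpKind::Relu, "", 0, lvl, -1);
    op(OpKind::Conv, pre + "_conv2", 3, lvl, -1);
    op(OpKind::Relu, "", 0, lvl, -1);
    if (d > 1) {
      op(OpKind::TConv, pre + "_transconv", 2, lvl, -1);
      op(OpKind::Concat, "", 0, lvl - 1, d - 2);
    }
  }
  op(OpKind::Conv, "convlast", 1, 0, -1);
  op(OpKind::Softmax, "", 0, 0, -1);
  return p;
}

// ---------------------------------------------------------------------------
// templated tensor ops

// Fill the im2col matrix for one z-slice of one batch item.
// X: (Cin, N*B); Kc: (27*Cin, H*W) preallocated; out-of-range entries are
// zeroed explicitly (no full-matrix clear), so interior slices touch almost
// no padding memory.
template <typename eT>
static void im2col_slice(const Mat<eT>& X, Mat<eT>& Kc, const LevelDims& dm,
                         int colbase, int z, int Cin) {
  const size_t cb = sizeof(eT) * Cin;
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const int zz = z + dz;
    const int row0 = o * Cin;
    if (zz < 0 || zz >= dm.D) {
      for (int v = 0; v < dm.H * dm.W; ++v)
        std::memset(Kc.colptr(v) + row0, 0, cb);
      continue;
    }
    for (int y = 0; y < dm.W; ++y) {
      const int yy = y + dy;
      if (yy < 0 || yy >= dm.W) {
        for (int x = 0; x < dm.H; ++x)
          std::memset(Kc.colptr(x + dm.H * y) + row0, 0, cb);
        continue;
      }
      const int x0 = std::max(0, -dx), x1 = std::min(dm.H - 1, dm.H - 1 - dx);
      for (int x = 0; x < x0; ++x)
        std::memset(Kc.colptr(x + dm.H * y) + row0, 0, cb);
      for (int x = x1 + 1; x < dm.H; ++x)
        std::memset(Kc.colptr(x + dm.H * y) + row0, 0, cb);
      for (int x = x0; x <= x1; ++x) {
        const int src = colbase + (x + dx) + dm.H * (yy + dm.W * zz);
        std::memcpy(Kc.colptr(x + dm.H * y) + row0, X.colptr(src), cb);
      }
    }
  }
}

template <typename eT>
static Mat<eT> conv_forward(const Mat<eT>& X, const Mat<eT>& Wm,
                            const Col<eT>& b, const LevelDims& dm, int B,
                            int k) {
  const int Cout = Wm.n_rows;
  if (k == 1) {
    Mat<eT> Y = Wm * X;
    Y.each_col() += b;
    return Y;
  }
  const int Cin = Wm.n_cols / 27;
  const int N = dm.N(), HW = dm.H * dm.W;
  Mat<eT> Y(Cout, (uword)N * B);
  Mat<eT> Kc(27 * Cin, HW);
  for (int bi = 0; bi < B; ++bi) {
    for (int z = 0; z < dm.D; ++z) {
      im2col_slice(X, Kc, dm, bi * N, z, Cin);
      // GEMM directly into the output slab (no temporary)
      Mat<eT> Yv(Y.colptr((uword)bi * N + (uword)z * HW), Cout, HW, false, true);
      Yv = Wm * Kc;
    }
  }
  Y.each_col() += b;
  return Y;
}

template <typename eT>
static void conv_backward(const Mat<eT>& X, const Mat<eT>& Wm,
                          const Mat<eT>& dY, const LevelDims& dm, int B, int k,
                          Mat<eT>& dX, Mat<eT>& dW, Col<eT>& db) {
  const int Cout = Wm.n_rows;
  db = sum(dY, 1);
  if (k == 1) {
    dX = Wm.t() * dY;
    dW = dY * X.t();
    return;
  }
  const int Cin = Wm.n_cols / 27;
  const int N = dm.N(), HW = dm.H * dm.W;
  dW.zeros(Cout, 27 * Cin);
  Mat<eT> Kc(27 * Cin, HW);
  for (int bi = 0; bi < B; ++bi) {
    for (int z = 0; z < dm.D; ++z) {
      im2col_slice(X, Kc, dm, bi * N, z, Cin);
      const Mat<eT> dYs(const_cast<eT*>(dY.colptr((uword)bi * N + (uword)z * HW)),
                        Cout, HW, false, true);
      dW += dYs * Kc.t();
    }
  }
  // dX is the 'full' correlation of dY with the spatially flipped, transposed
  // kernel: dX(ci, v) = sum_o sum_co W(co, o*Cin+ci) dY(co, v + off(o)), i.e.
  // a same-padded convolution of dY with Wback(ci, o'*Cout+co) = W(co, o*Cin+ci),
  // o' = 26 - o. GEMM-bound instead of a scalar scatter-add.
  Mat<eT> Wback(Cin, 27 * Cout);
  for (int o = 0; o < 27; ++o)
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        Wback(ci, (26 - o) * Cout + co) = Wm(co, o * Cin + ci);
  const Col<eT> zero_bias(Cin, fill::zeros);
  dX = conv_forward(dY, Wback, zero_bias, dm, B, 3);
}

template <typename eT>
static Mat<eT> pool_forward(const Mat<eT>& X, const LevelDims& dm, int B,
                            umat& argmax) {
  const int C = X.n_rows;
  const int Ho = dm.H / 2, Wo = dm.W / 2, Do = dm.D / 2;
  const int No = Ho * Wo * Do, N = dm.N();
  Mat<eT> Y(C, (uword)No * B);
  argmax.set_size(C, (uword)No * B);
  for (int bi = 0; bi < B; ++bi)
    for (int z = 0; z < Do; ++z)
      for (int y = 0; y < Wo; ++y)
        for (int x = 0; x < Ho; ++x) {
          const uword j = (uword)bi * No + x + Ho * (y + (uword)Wo * z);
          eT* yp = Y.colptr(j);
          uword* ap = argmax.colptr(j);
          bool first = true;
          for (int rz = 0; rz < 2; ++rz)
            for (int ry = 0; ry < 2; ++ry)
              for (int rx = 0; rx < 2; ++rx) {
                const uword src =
                    (uword)bi * N + (2 * x + rx) +
                    dm.H * ((2 * y + ry) + (uword)dm.W * (2 * z + rz));
                const eT* xp = X.colptr(src);
                if (first) {
                  for (int c = 0; c < C; ++c) { yp[c] = xp[c]; ap[c] = src; }
                  first = false;
                } else {
                  for (int c = 0; c < C; ++c)
                    if (xp[c] > yp[c]) { yp[c] = xp[c]; ap[c] = src; }
                }
              }
        }
  return Y;
}

template <typename eT>
static Mat<eT> pool_backward(const Mat<eT>& dY, const umat& argmax,
                             const LevelDims& dm, int B) {
  const int C = dY.n_rows;
  Mat<eT> dX(C, (uword)dm.N() * B, fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j) {
    const eT* dp = dY.colptr(j);
    const uword* ap = argmax.colptr(j);
    for (int c = 0; c < C; ++c) dX(c, ap[c]) += dp[c];
  }
  return dX;
}

template <typename eT>
static Mat<eT> tconv_forward(const Mat<eT>& X,
                             const std::array<Mat<eT>, 8>& Wo,
                             const Col<eT>& b, const LevelDims& dm, int B) {
  const int Cout = Wo[0].n_rows;
  const int N = dm.N(), Ho = 2 * dm.H, Wd = 2 * dm.W;
  const int No = 8 * N;
  Mat<eT> Y(Cout, (uword)No * B);
  for (int o = 0; o < 8; ++o) {
    const int rx = o % 2, ry = (o / 2) % 2, rz = o / 4;
    const Mat<eT> T = Wo[o] * X;  // (Cout, N*B)
    for (int bi = 0; bi < B; ++bi)
      for (int z = 0; z < dm.D; ++z)
        for (int y = 0; y < dm.W; ++y)
          for (int x = 0; x < dm.H; ++x) {
            const uword src = (uword)bi * N + x + dm.H * (y + (uword)dm.W * z);
            const uword dst = (uword)bi * No + (2 * x + rx) +
                              Ho * ((2 * y + ry) + (uword)Wd * (2 * z + rz));
            std::memcpy(Y.colptr(dst), T.colptr(src), sizeof(eT) * Cout);
          }
  }
  Y.each_col() += b;
  return Y;
}

template <typename eT>
static void tconv_backward(const Mat<eT>& X, const std::array<Mat<eT>, 8>& Wo,
                           const Mat<eT>& dY, const LevelDims& dm, int B,
                           Mat<eT>& dX, std::array<Mat<eT>, 8>& dW,
                           Col<eT>& db) {
  const int Cin = Wo[0].n_cols, Cout = Wo[0].n_rows;
  const int N = dm.N(), Ho = 2 * dm.H, Wd = 2 * dm.W;
  const int No = 8 * N;
  db = sum(dY, 1);
  dX.zeros(Cin, (uword)N * B);
  Mat<eT> G(Cout, (uword)N * B);
  for (int o = 0; o < 8; ++o) {
    const int rx = o % 2, ry = (o / 2) % 2, rz = o / 4;
    for (int bi = 0; bi < B; ++bi)
      for (int z = 0; z < dm.D; ++z)
        for (int y = 0; y < dm.W; ++y)
          for (int x = 0; x < dm.H; ++x) {
            const uword dst = (uword)bi * N + x + dm.H * (y + (uword)dm.W * z);
            const uword src = (uword)bi * No + (2 * x + rx) +
                              Ho * ((2 * y + ry) + (uword)Wd * (2 * z + rz));
            std::memcpy(G.colptr(dst), dY.colptr(src), sizeof(eT) * Cout);
          }
    dW[o] = G * X.t();
    dX += Wo[o].t() * G;
  }
}

template <typename eT>
static void relu_inplace(Mat<eT>& Y, eT slope) {
  eT* p = Y.memptr();
  for (uword i = 0; i < Y.n_elem; ++i)
    if (p[i] < eT(0)) p[i] *= slope;
}

// Mask from the ReLU *output*: for slope in [0, 1), Y > 0 iff the
// pre-activation was > 0, so the stored post-activation suffices.
template <typename eT>
static void relu_backward_inplace(const Mat<eT>& Y, Mat<eT>& dY, eT slope) {
  eT* p = dY.memptr();
  const eT* yp = Y.memptr();
  for (uword i = 0; i < dY.n_elem; ++i)
    if (yp[i] <= eT(0)) p[i] *= slope;
}

template <typename eT>
static void softmax_inplace(Mat<eT>& Y) {
  const int K = Y.n_rows;
  for (uword j = 0; j < Y.n_cols; ++j) {
    eT* p = Y.colptr(j);
    eT mx = p[0];
    for (int k = 1; k < K; ++k) mx = std::max(mx, p[k]);
    eT s = eT(0);
    for (int k = 0; k < K; ++k) { p[k] = std::exp(p[k] - mx); s += p[k]; }
    for (int k = 0; k < K; ++k) p[k] /= s;
  }
}

// ---------------------------------------------------------------------------
// parameter containers

template <typename eT>
struct Params {
  std::map<std::string, Mat<eT>> convW;
  std::map<std::string, Col<eT>> convB;
  std::map<std::string, std::array<Mat<eT>, 8>> tconvW;
  std::map<std::string, Col<eT>> tconvB;
  std::map<std::string, Col<eT>> bnScale, bnOffset, bnRMean, bnRVar;
};

template <typename eT>
static Col<eT> as_col(SEXP s) {
  Rcpp::NumericVector v(s);
  Col<eT> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (eT)v[i];
  return out;
}

template <typename eT>
static Params<eT> load_params(const Rcpp::List& rp, const Rcpp::List& bn,
                              const NetPlan& plan) {
  Params<eT> P;
  for (const auto& kv : plan.convs) {
    const ConvDef& cd = kv.second;
    Rcpp::NumericVector w = rp[cd.name + "_W"];
    const int kk = cd.k * cd.k * cd.k;
    if ((R_xlen_t)w.size() != (R_xlen_t)kk * cd.cin * cd.cout)
      Rcpp::stop("bad size for %s_W", cd.name.c_str());
    Mat<eT> Wm(cd.cout, kk * cd.cin);
    for (int co = 0; co < cd.cout; ++co)
      for (int ci = 0; ci < cd.cin; ++ci)
        for (int o = 0; o < kk; ++o)
          Wm(co, o * cd.cin + ci) =
              (eT)w[o + (R_xlen_t)kk * (ci + (R_xlen_t)cd.cin * co)];
    P.convW[cd.name] = std::move(Wm);
    P.convB[cd.name] = as_col<eT>(rp[cd.name + "_b"]);
  }
  for (const auto& kv : plan.tconvs) {
    const TConvDef& td = kv.second;
    Rcpp::NumericVector w = rp[td.name + "_W"];
    if ((R_xlen_t)w.size() != (R_xlen_t)8 * td.c * td.c)
      Rcpp::stop("bad size for %s_W", td.name.c_str());
    std::array<Mat<eT>, 8> Wo;
    for (int o = 0; o < 8; ++o) Wo[o].set_size(td.c, td.c);
    for (int co = 0; co < td.c; ++co)
      for (int ci = 0; ci < td.c; ++ci)
        for (int o = 0; o < 8; ++o)
          Wo[o](co, ci) = (eT)w[o + (R_xlen_t)8 * (ci + (R_xlen_t)td.c * co)];
    P.tconvW[td.name] = std::move(Wo);
    P.tconvB[td.name] = as_col<eT>(rp[td.name + "_b"]);
  }
  Rcpp::List rmean = bn["mean"], rvar = bn["var"];
  for (const auto& kv : plan.bns) {
    const std::string& n = kv.first;
    P.bnScale[n] = as_col<eT>(rp[n + "_scale"]);
    P.bnOffset[n] = as_col<eT>(rp[n + "_offset"]);
    P.bnRMean[n] = as_col<eT>(rmean[n]);
    P.bnRVar[n] = as_col<eT>(rvar[n]);
  }
  return P;
}

// ---------------------------------------------------------------------------
// forward / backward through the op tape

template <typename eT>
struct TapeEntry {
  Mat<eT> out;        // op output
  umat argmax;        // pool
  Mat<eT> xhat;       // batchnorm
  Col<eT> invstd;
  int concat_top = 0; // rows contributed by the transposed conv in a concat
};

template <typename eT>
struct Gradients {
  std::map<std::string, Mat<eT>> convW;
  std::map<std::string, Col<eT>> convB;
  std::map<std::string, std::array<Mat<eT>, 8>> tconvW;
  std::map<std::string, Col<eT>> tconvB;
  std::map<std::string, Col<eT>> bnScale, bnOffset;
};

// Forward through all ops. If `tape` is non-null every op output (plus
// pool/batchnorm caches) is recorded for the backward pass; batchnorm then
// uses batch statistics and updates the running statistics in P with rate
// `bn_momentum`. Without a tape, batchnorm uses the running statistics
// (inference mode).
template <typename eT>
static Mat<eT> run_forward(Params<eT>& P, const NetPlan& plan,
                           const Mat<eT>& X0,
                           const std::vector<LevelDims>& lv, int B,
                           std::vector<TapeEntry<eT>>* tape,
                           double bn_momentum) {
  const eT slope = (eT)plan.leaky;
  Mat<eT> owned;
  const Mat<eT>* cur = &X0;
  std::array<Mat<eT>, 3> skips;
  if (tape) tape->resize(plan.ops.size());
  for (size_t i = 0; i < plan.ops.size(); ++i) {
    const OpDef& op = plan.ops[i];
    // ReLU and softmax modify their input in place (stealing the previous
    // tape entry): their backward passes only need their own output.
    if (op.kind == OpKind::Relu || op.kind == OpKind::Softmax) {
      Mat<eT> stolen;
      if (tape) stolen = (i > 0) ? std::move((*tape)[i - 1].out) : X0;
      else stolen = std::move(owned);
      if (op.kind == OpKind::Relu) relu_inplace(stolen, slope);
      else softmax_inplace(stolen);
      if (tape) {
        (*tape)[i].out = std::move(stolen);
        cur = &(*tape)[i].out;
      } else {
        owned = std::move(stolen);
        cur = &owned;
      }
      continue;
    }
    Mat<eT> nxt;
    umat argmax;
    Mat<eT> xhat_cache;
    Col<eT> invstd_cache;
    int concat_top = 0;
    switch (op.kind) {
      case OpKind::Conv:
        nxt = conv_forward(*cur, P.convW.at(op.name), P.convB.at(op.name),
                           lv[op.level], B, op.k);
        break;
      case OpKind::BN: {
        const Col<eT>& gamma = P.bnScale.at(op.name);
        const Col<eT>& beta = P.bnOffset.at(op.name);
        if (tape) {
          Col<eT> mu = mean(*cur, 1);
          Col<eT> var = mean(square(*cur), 1) - square(mu);
          var.transform([](eT v) { return v < eT(0) ? eT(0) : v; });
          Col<eT> invstd = eT(1) / sqrt(var + (eT)BN_EPS);
          Mat<eT> xh = *cur;
          xh.each_col() -= mu;
          xh.each_col() %= invstd;
          nxt = xh;
          nxt.each_col() %= gamma;
          nxt.each_col() += beta;
          P.bnRMean.at(op.name) =
              (eT)(1 - bn_momentum) * P.bnRMean.at(op.name) + (eT)bn_momentum * mu;
          P.bnRVar.at(op.name) =
              (eT)(1 - bn_momentum) * P.bnRVar.at(op.name) + (eT)bn_momentum * var;
          xhat_cache = std::move(xh);
          invstd_cache = std::move(invstd);
        } else {
          Col<eT> invstd = eT(1) / sqrt(P.bnRVar.at(op.name) + (eT)BN_EPS);
          nxt = *cur;
          nxt.each_col() -= P.bnRMean.at(op.name);
          nxt.each_col() %= invstd % gamma;
          nxt.each_col() += beta;
        }
        break;
      }
      case OpKind::Relu:  // handled above
        break;
      case OpKind::Pool:
        nxt = pool_forward(*cur, lv[op.level], B, argmax);
        break;
      case OpKind::TConv:
        nxt = tconv_forward(*cur, P.tconvW.at(op.name), P.tconvB.at(op.name),
                            lv[op.level], B);
        break;
      case OpKind::Save:
        skips[op.slot] = *cur;
        nxt = *cur;
        break;
      case OpKind::Concat:
        concat_top = cur->n_rows;
        nxt = join_cols(*cur, skips[op.slot]);
        break;
      case OpKind::Softmax:  // handled above
        break;
    }
    if (tape) {
      TapeEntry<eT>& te = (*tape)[i];
      te.out = std::move(nxt);
      te.argmax = std::move(argmax);
      te.xhat = std::move(xhat_cache);
      te.invstd = std::move(invstd_cache);
      te.concat_top = concat_top;
      cur = &te.out;
    } else {
      owned = std::move(nxt);
      cur = &owned;
    }
  }
  return *cur;
}

template <typename eT>
static Gradients<eT> run_backward(const Params<eT>& P, const NetPlan& plan,
                                  const Mat<eT>& X0,
                                  const std::vector<LevelDims>& lv, int B,
                                  const std::vector<TapeEntry<eT>>& tape,
                                  Mat<eT> dcur) {
  const eT slope = (eT)plan.leaky;
  Gradients<eT> G;
  std::array<Mat<eT>, 3> dskips;
  for (int i = (int)plan.ops.size() - 1; i >= 0; --i) {
    const OpDef& op = plan.ops[i];
    const Mat<eT>& input = (i == 0) ? X0 : tape[i - 1].out;
    switch (op.kind) {
      case OpKind::Conv: {
        Mat<eT> dX, dW;
        Col<eT> db;
        conv_backward(input, P.convW.at(op.name), dcur, lv[op.level], B, op.k,
                      dX, dW, db);
        G.convW[op.name] = std::move(dW);
        G.convB[op.name] = std::move(db);
        dcur = std::move(dX);
        break;
      }
      case OpKind::BN: {
        const TapeEntry<eT>& te = tape[i];
        const Col<eT>& gamma = P.bnScale.at(op.name);
        G.bnScale[op.name] = sum(dcur % te.xhat, 1);
        G.bnOffset[op.name] = sum(dcur, 1);
        Mat<eT> dxhat = dcur;
        dxhat.each_col() %= gamma;
        Col<eT> m1 = mean(dxhat, 1);
        Col<eT> m2 = mean(dxhat % te.xhat, 1);
        Mat<eT> dX = std::move(dxhat);
        dX.each_col() -= m1;
        dX -= te.xhat.each_col() % m2;
        dX.each_col() %= te.invstd;
        dcur = std::move(dX);
        break;
      }
      case OpKind::Relu:
        relu_backward_inplace(tape[i].out, dcur, slope);
        break;
      case OpKind::Pool:
        dcur = pool_backward(dcur, tape[i].argmax, lv[op.level], B);
        break;
      case OpKind::TConv: {
        Mat<eT> dX;
        std::array<Mat<eT>, 8> dW;
        Col<eT> db;
        tconv_backward(input, P.tconvW.at(op.name), dcur, lv[op.level], B, dX,
                       dW, db);
        G.tconvW[op.name] = std::move(dW);
        G.tconvB[op.name] = std::move(db);
        dcur = std::move(dX);
        break;
      }
      case OpKind::Save:
        if (dskips[op.slot].n_elem > 0) dcur += dskips[op.slot];
        break;
      case OpKind::Concat: {
        const int top = tape[i].concat_top;
        dskips[op.slot] = dcur.rows(top, dcur.n_rows - 1);
        dcur = dcur.rows(0, top - 1);
        break;
      }
      case OpKind::Softmax: {
        const Mat<eT>& Y = tape[i].out;
        for (uword j = 0; j < Y.n_cols; ++j) {
          const eT* yp = Y.colptr(j);
          eT* dp = dcur.colptr(j);
          eT dot = eT(0);
          for (uword k = 0; k < Y.n_rows; ++k) dot += dp[k] * yp[k];
          for (uword k = 0; k < Y.n_rows; ++k) dp[k] = yp[k] * (dp[k] - dot);
        }
        break;
      }
    }
  }
  return G;
}

// Class-weighted generalized Dice loss, one term per batch item, averaged.
// Y: (K, N*B) softmax output; labels: N*B ints in 0..K-1 (column order).
// Returns the mean loss and fills dY (same shape as Y).
template <typename eT>
static double dice_loss_grad(const Mat<eT>& Y, const Rcpp::IntegerVector& labels,
                             int K, int N, int B, Mat<eT>& dY,
                             std::vector<double>& per_patch) {
  dY.zeros(Y.n_rows, Y.n_cols);
  per_patch.assign(B, 0.0);
  double total = 0.0;
  for (int bi = 0; bi < B; ++bi) {
    std::vector<double> area(K, 0.0), inter(K, 0.0), ysq(K, 0.0);
    const uword base = (uword)bi * N;
    for (int v = 0; v < N; ++v) {
      const int lab = labels[base + v];
      const eT* yp = Y.colptr(base + v);
      area[lab] += 1.0;
      inter[lab] += (double)yp[lab];
      for (int k = 0; k < K; ++k) ysq[k] += (double)yp[k] * (double)yp[k];
    }
    std::vector<double> w(K);
    for (int k = 0; k < K; ++k)
      w[k] = area[k] > 0 ? 1.0 / (area[k] * area[k]) : 1.0;
    double num = 0.0, den = LOSS_SMOOTH;
    for (int k = 0; k < K; ++k) {
      num += 2.0 * w[k] * inter[k];
      den += w[k] * (ysq[k] + area[k]);  // sum T^2 = area for one-hot T
    }
    const double L = 1.0 - num / den;
    per_patch[bi] = L;
    total += L;
    // dL/dY_km = 2 w_k (num * Y_km - T_km * den) / den^2, averaged over batch
    const double scale = 1.0 / ((double)B * den * den);
    for (int v = 0; v < N; ++v) {
      const int lab = labels[base + v];
      const eT* yp = Y.colptr(base + v);
      eT* dp = dY.colptr(base + v);
      for (int k = 0; k < K; ++k) {
        double g = 2.0 * w[k] * (num * (double)yp[k] -
                                 ((k == lab) ? den : 0.0));
        dp[k] = (eT)(g * scale);
      }
    }
  }
  return total / B;
}

// ---------------------------------------------------------------------------
// R interface helpers

struct InputDims {
  LevelDims l0;
  int C, B, K;
  std::vector<LevelDims> levels;
};

static InputDims check_input(const Rcpp::NumericVector& x, const NetPlan& plan) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 5) Rcpp::stop("input must be a 5D (H, W, D, C, B) array");
  InputDims id;
  id.l0 = LevelDims{d[0], d[1], d[2]};
  id.C = d[3];
  id.B = d[4];
  id.K = plan.K;
  if (id.C != plan.cin)
    Rcpp::stop("input has %d channels; the network expects %d", id.C, plan.cin);
  if (d[0] % 8 || d[1] % 8 || d[2] % 8)
    Rcpp::stop("spatial input dimensions must be divisible by 8");
  id.levels.push_back(id.l0);
  for (int i = 0; i < 3; ++i) {
    LevelDims prev = id.levels.back();
    id.levels.push_back(LevelDims{prev.H / 2, prev.W / 2, prev.D / 2});
  }
  return id;
}

template <typename eT>
static Mat<eT> input_to_mat(const Rcpp::NumericVector& x, const InputDims& id) {
  const R_xlen_t N = id.l0.N();
  Mat<eT> X(id.C, N * id.B);
  for (int bi = 0; bi < id.B; ++bi)
    for (int c = 0; c < id.C; ++c) {
      const double* src = &x[N * (c + (R_xlen_t)id.C * bi)];
      for (R_xlen_t v = 0; v < N; ++v) X(c, (uword)bi * N + v) = (eT)src[v];
    }
  return X;
}

template <typename eT>
static Rcpp::NumericVector probs_to_array(const Mat<eT>& probs,
                                          const InputDims& id) {
  const R_xlen_t N = id.l0.N();
  Rcpp::NumericVector out(N * id.K * id.B);
  for (int bi = 0; bi < id.B; ++bi)
    for (int k = 0; k < id.K; ++k) {
      double* dst = &out[N * (k + (R_xlen_t)id.K * bi)];
      for (R_xlen_t v = 0; v < N; ++v) dst[v] = (double)probs(k, (uword)bi * N + v);
    }
  out.attr("dim") = Rcpp::IntegerVector::create(id.l0.H, id.l0.W, id.l0.D,
                                                id.K, id.B);
  return out;
}

static NetPlan plan_from_spec(const Rcpp::List& spec) {
  return make_plan(Rcpp::as<int>(spec["base"]), Rcpp::as<int>(spec["cin"]),
                   Rcpp::as<int>(spec["K"]), Rcpp::as<double>(spec["leaky"]));
}

template <typename eT>
static Rcpp::NumericVector grad_conv_to_r(const Mat<eT>& dW, const ConvDef& cd) {
  const int kk = cd.k * cd.k * cd.k;
  Rcpp::NumericVector out((R_xlen_t)kk * cd.cin * cd.cout);
  for (int co = 0; co < cd.cout; ++co)
    for (int ci = 0; ci < cd.cin; ++ci)
      for (int o = 0; o < kk; ++o)
        out[o + (R_xlen_t)kk * (ci + (R_xlen_t)cd.cin * co)] =
            (double)dW(co, o * cd.cin + ci);
  out.attr("dim") =
      Rcpp::IntegerVector::create(cd.k, cd.k, cd.k, cd.cin, cd.cout);
  return out;
}

template <typename eT>
static Rcpp::NumericVector grad_tconv_to_r(const std::array<Mat<eT>, 8>& dW,
                                           const TConvDef& td) {
  Rcpp::NumericVector out((R_xlen_t)8 * td.c * td.c);
  for (int co = 0; co < td.c; ++co)
    for (int ci = 0; ci < td.c; ++ci)
      for (int o = 0; o < 8; ++o)
        out[o + (R_xlen_t)8 * (ci + (R_xlen_t)td.c * co)] =
            (double)dW[o](co, ci);
  out.attr("dim") = Rcpp::IntegerVector::create(2, 2, 2, td.c, td.c);
  return out;
}

template <typename eT>
static Rcpp::NumericVector col_to_r(const Col<eT>& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

template <typename eT>
static Rcpp::NumericVector forward_impl(const Rcpp::List& params,
                                        const Rcpp::List& bn_state,
                                        const Rcpp::List& spec,
                                        const Rcpp::NumericVector& x,
                                        bool training) {
  NetPlan plan = plan_from_spec(spec);
  InputDims id = check_input(x, plan);
  Params<eT> P = load_params<eT>(params, bn_state, plan);
  Mat<eT> X0 = input_to_mat<eT>(x, id);
  Mat<eT> probs;
  if (training) {
    std::vector<TapeEntry<eT>> tape;
    probs = run_forward(P, plan, X0, id.levels, id.B, &tape, 0.0);
  } else {
    probs = run_forward(P, plan, X0, id.levels, id.B,
                        (std::vector<TapeEntry<eT>>*)nullptr, 0.0);
  }
  return probs_to_array(probs, id);
}

template <typename eT>
static Rcpp::List fwd_bwd_impl(const Rcpp::List& params,
                               const Rcpp::List& bn_state,
                               const Rcpp::List& spec,
                               const Rcpp::NumericVector& x,
                               const Rcpp::IntegerVector& labels,
                               double bn_momentum) {
  NetPlan plan = plan_from_spec(spec);
  InputDims id = check_input(x, plan);
  if ((R_xlen_t)labels.size() != (R_xlen_t)id.l0.N() * id.B)
    Rcpp::stop("labels size does not match input spatial size");
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] < 0 || labels[i] >= plan.K)
      Rcpp::stop("labels must lie in 0 .. K-1");
  Params<eT> P = load_params<eT>(params, bn_state, plan);
  Mat<eT> X0 = input_to_mat<eT>(x, id);
  std::vector<TapeEntry<eT>> tape;
  Mat<eT> probs = run_forward(P, plan, X0, id.levels, id.B, &tape, bn_momentum);
  Mat<eT> dY;
  std::vector<double> per_patch;
  const double loss =
      dice_loss_grad(probs, labels, plan.K, id.l0.N(), id.B, dY, per_patch);
  Gradients<eT> G =
      run_backward(P, plan, X0, id.levels, id.B, tape, std::move(dY));

  // grads in the exact order of the R-side parameter list
  Rcpp::List grads;
  auto add_conv = [&](const std::string& n) {
    grads[n + "_W"] = grad_conv_to_r(G.convW.at(n), plan.convs.at(n));
    grads[n + "_b"] = col_to_r(G.convB.at(n));
  };
  for (int e = 1; e <= 3; ++e) {
    const std::string pre = "en" + std::to_string(e);
    add_conv(pre + "_conv1");
    grads[pre + "_bn1_scale"] = col_to_r(G.bnScale.at(pre + "_bn1"));
    grads[pre + "_bn1_offset"] = col_to_r(G.bnOffset.at(pre + "_bn1"));
    add_conv(pre + "_conv2");
  }
  for (int d = 4; d >= 1; --d) {
    const std::string pre = "de" + std::to_string(d);
    add_conv(pre + "_conv1");
    add_conv(pre + "_conv2");
    if (d > 1) {
      grads[pre + "_transconv_W"] =
          grad_tconv_to_r(G.tconvW.at(pre + "_transconv"),
                          plan.tconvs.at(pre + "_transconv"));
      grads[pre + "_transconv_b"] = col_to_r(G.tconvB.at(pre + "_transconv"));
    }
  }
  add_conv("convlast");

  Rcpp::List new_mean, new_var;
  for (const auto& kv : plan.bns) {
    new_mean[kv.first] = col_to_r(P.bnRMean.at(kv.first));
    new_var[kv.first] = col_to_r(P.bnRVar.at(kv.first));
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("per_patch_loss") = Rcpp::wrap(per_patch),
      Rcpp::Named("grads") = grads,
      Rcpp::Named("bn_state") = Rcpp::List::create(
          Rcpp::Named("mean") = new_mean, Rcpp::Named("var") = new_var));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_unet_forward(Rcpp::List params, Rcpp::List bn_state,
                                     Rcpp::List spec, Rcpp::NumericVector x,
                                     bool training, bool use_double) {
  if (use_double)
    return forward_impl<double>(params, bn_state, spec, x, training);
  return forward_impl<float>(params, bn_state, spec, x, training);
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_fwd_bwd(Rcpp::List params, Rcpp::List bn_state,
                            Rcpp::List spec, Rcpp::NumericVector x,
                            Rcpp::IntegerVector labels, double bn_momentum,
                            bool use_double) {
  if (use_double)
    return fwd_bwd_impl<double>(params, bn_state, spec, x, labels, bn_momentum);
  return fwd_bwd_impl<float>(params, bn_state, spec, x, labels, bn_momentum);
}
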