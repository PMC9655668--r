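// Instruction-tape CNN engine: forward and hand-derived backward passes for
// the layer vocabulary the detector needs (conv via im2col+GEMM, depthwise
// conv, batch norm, ReLU/SiLU/sigmoid, global avg/max pool, broadcast
// multiply, residual add, channel mean/max stacking, 1-D channel conv).
// Tensors use NCHW layout with the spatial index fastest so each (image,
// channel) plane is contiguous and 1x1 convolutions reduce to a single GEMM.
// The engine is templated: float for training throughput, double for
// finite-difference gradient checks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <chrono>
#include <cstdlib>

using namespace Rcpp;

// fast single-precision exp (range reduction + degree-6 Taylor on
// [-ln2/2, ln2/2]; relative error ~1e-7, auto-vectorizable)
static inline float fexp(float x) {
  x = std::min(std::max(x, -87.0f), 88.0f);
  float t = x * 1.4426950408889634f;
  int32_t ki = (int32_t)(t + 16384.5f) - 16384;  // floor(t + 0.5), |t| < 127
  float r = x - (float)ki * 0.6931471805599453f;
  float p = 1.0f + r * (1.0f + r * (0.5f + r * (0.16666667f +
            r * (0.041666668f + r * (0.008333334f + r * 0.0013888889f)))));
  return p * __builtin_bit_cast(float, (ki + 127) << 23);
}
template <typename T> static inline T texp(T x) { return std::exp(x); }
template <> inline float texp<float>(float x) { return fexp(x); }


// ---- hot elementwise kernels --------------------------------------------
// Generic templates serve the double (gradient-check) path; float overloads
// carry target_clones so the runtime picks an AVX2 version when available
// (the shipped baseline ISA stays conservative).

#define ENG_CLONE __attribute__((target_clones("arch=x86-64-v3", "avx2", "default")))

template <typename T> static void k_silu(const T* x, T* o, size_t n) {
  for (size_t t = 0; t < n; ++t) {
    T s = (T)1 / ((T)1 + std::exp(-x[t]));
    o[t] = x[t] * s;
  }
}
ENG_CLONE static void k_silu(const float* x, float* o, size_t n) {
  for (size_t t = 0; t < n; ++t) {
    float s = 1.0f / (1.0f + fexp(-x[t]));
    o[t] = x[t] * s;
  }
}
template <typename T> static void k_silu_b(const T* x, const T* g, T* dx, size_t n) {
  for (size_t t = 0; t < n; ++t) {
    T s = (T)1 / ((T)1 + std::exp(-x[t]));
    dx[t] += g[t] * s * ((T)1 + x[t] * ((T)1 - s));
  }
}
ENG_CLONE static void k_silu_b(const float* x, const float* g, float* dx, size_t n) {
  for (size_t t = 0; t < n; ++t) {
    float s = 1.0f / (1.0f + fexp(-x[t]));
    dx[t] += g[t] * s * (1.0f + x[t] * (1.0f - s));
  }
}
template <typename T> static void k_sigm(const T* x, T* o, size_t n) {
  for (size_t t = 0; t < n; ++t) o[t] = (T)1 / ((T)1 + std::exp(-x[t]));
}
ENG_CLONE static void k_sigm(const float* x, float* o, size_t n) {
  for (size_t t = 0; t < n; ++t) o[t] = 1.0f / (1.0f + fexp(-x[t]));
}
template <typename T> static void k_sigm_b(const T* o, const T* g, T* dx, size_t n) {
  for (size_t t = 0; t < n; ++t) dx[t] += g[t] * o[t] * ((T)1 - o[t]);
}
template <typename T> static void k_relu(const T* x, T* o, size_t n) {
  for (size_t t = 0; t < n; ++t) o[t] = x[t] > 0 ? x[t] : (T)0;
}
template <typename T> static void k_relu_b(const T* x, const T* g, T* dx, size_t n) {
  for (size_t t = 0; t < n; ++t) if (x[t] > 0) dx[t] += g[t];
}
template <typename T>
static void k_bnstats(const T* x, size_t n, double& acc, double& acc2) {
  double a1 = 0, a2 = 0;
  for (size_t t = 0; t < n; ++t) { a1 += x[t]; a2 += (double)x[t] * x[t]; }
  acc += a1; acc2 += a2;
}
ENG_CLONE static void k_bnstats(const float* x, size_t n, double& acc, double& acc2) {
  size_t t = 0;
  while (t < n) {
    size_t e = t + 65536; if (e > n) e = n;
    float a1 = 0, a2 = 0;
    for (; t < e; ++t) { a1 += x[t]; a2 += x[t] * x[t]; }
    acc += a1; acc2 += a2;
  }
}
template <typename T> static void k_axpb(const T* x, T* o, size_t n, T a, T b) {
  for (size_t t = 0; t < n; ++t) o[t] = a * x[t] + b;
}
ENG_CLONE static void k_axpb(const float* x, float* o, size_t n, float a, float b) {
  for (size_t t = 0; t < n; ++t) o[t] = a * x[t] + b;
}
template <typename T>
static void k_bnred(const T* x, const T* g, size_t n, T m, T is,
                    double& dg, double& db) {
  double a1 = 0, a2 = 0;
  for (size_t t = 0; t < n; ++t) { a1 += (double)g[t] * (x[t] - m) * is; a2 += g[t]; }
  dg += a1; db += a2;
}
ENG_CLONE static void k_bnred(const float* x, const float* g, size_t n,
                              float m, float is, double& dg, double& db) {
  size_t t = 0;
  while (t < n) {
    size_t e = t + 65536; if (e > n) e = n;
    float a1 = 0, a2 = 0;
    for (; t < e; ++t) { a1 += g[t] * (x[t] - m) * is; a2 += g[t]; }
    dg += a1; db += a2;
  }
}
template <typename T>
static void k_bndx(const T* x, const T* g, T* dx, size_t n, T m, T is,
                   T ta, T c1, T c2) {
  for (size_t t = 0; t < n; ++t)
    dx[t] += ta * g[t] - c1 - (x[t] - m) * is * c2;
}
ENG_CLONE static void k_bndx(const float* x, const float* g, float* dx,
                             size_t n, float m, float is, float ta, float c1,
                             float c2) {
  for (size_t t = 0; t < n; ++t)
    dx[t] += ta * g[t] - c1 - (x[t] - m) * is * c2;
}
template <typename T> static void k_axpy(T* o, const T* x, T w, int n) {
  for (int t = 0; t < n; ++t) o[t] += w * x[t];
}
ENG_CLONE static void k_axpy(float* o, const float* x, float w, int n) {
  for (int t = 0; t < n; ++t) o[t] += w * x[t];
}
template <typename T>
static T k_dotaxpy(T* dr, const T* r, const T* g, T w, int n) {
  T acc = 0;
  for (int t = 0; t < n; ++t) { acc += g[t] * r[t]; dr[t] += w * g[t]; }
  return acc;
}
ENG_CLONE static float k_dotaxpy(float* dr, const float* r, const float* g,
                                 float w, int n) {
  float acc = 0;
  for (int t = 0; t < n; ++t) { acc += g[t] * r[t]; dr[t] += w * g[t]; }
  return acc;
}
template <typename T> static void k_scale(const T* a, T* o, T g, size_t n) {
  for (size_t t = 0; t < n; ++t) o[t] = g * a[t];
}
ENG_CLONE static void k_scale(const float* a, float* o, float g, size_t n) {
  for (size_t t = 0; t < n; ++t) o[t] = g * a[t];
}
template <typename T>
static T k_scale_dot(const T* a, const T* g, T* da, T gch, size_t n) {
  T acc = 0;
  for (size_t t = 0; t < n; ++t) { da[t] += gch * g[t]; acc += g[t] * a[t]; }
  return acc;
}
ENG_CLONE static float k_scale_dot(const float* a, const float* g, float* da,
                                   float gch, size_t n) {
  float acc = 0;
  for (size_t t = 0; t < n; ++t) { da[t] += gch * g[t]; acc += g[t] * a[t]; }
  return acc;
}

enum OpCode {
  OP_CONV = 0, OP_DWCONV, OP_BN, OP_RELU, OP_SILU, OP_SIGMOID,
  OP_GAP, OP_GMP, OP_MUL, OP_ADD, OP_CHSTAT, OP_CONV1DCH
};

struct Instr {
  int op = 0;
  std::vector<int> in;  // value ids, 0-based
  int out = 0;
  std::vector<int> p;   // param ids, 0-based
  std::vector<int> s;   // state ids, 0-based
  std::vector<double> k;
};

static int op_code(const std::string& op) {
  if (op == "conv") return OP_CONV;
  if (op == "dwconv") return OP_DWCONV;
  if (op == "bn") return OP_BN;
  if (op == "relu") return OP_RELU;
  if (op == "silu") return OP_SILU;
  if (op == "sigmoid") return OP_SIGMOID;
  if (op == "gap") return OP_GAP;
  if (op == "gmp") return OP_GMP;
  if (op == "mul") return OP_MUL;
  if (op == "add") return OP_ADD;
  if (op == "chstat") return OP_CHSTAT;
  if (op == "conv1dch") return OP_CONV1DCH;
  stop("unknown engine op '%s'", op.c_str());
  return -1;
}

template <typename T> struct Tens {
  int n = 0, c = 0, h = 0, w = 0;
  arma::Col<T> v;
  bool alloc = false;
  void set(int N, int C, int H, int W) {
    n = N; c = C; h = H; w = W;
    v.zeros((arma::uword)N * C * H * W);
    alloc = true;
  }
  void setraw(int N, int C, int H, int W) {  // contents fully overwritten
    n = N; c = C; h = H; w = W;
    v.set_size((arma::uword)N * C * H * W);
    alloc = true;
  }
  size_t plane_sz() const { return (size_t)h * w; }
  T* plane(int in_, int ic) {
    return v.memptr() + ((size_t)in_ * c + ic) * plane_sz();
  }
  const T* plane(int in_, int ic) const {
    return v.memptr() + ((size_t)in_ * c + ic) * plane_sz();
  }
};

// ---- R <-> engine layout conversion -------------------------------------
// R arrays are column-major over dims (N, C, H, W); engine layout is
// ((n*C + c)*H + i)*W + j.

template <typename T>
static void r_to_eng(const NumericVector& a, Tens<T>& t) {
  IntegerVector d = a.attr("dim");
  int N = d[0], C = d[1], H = d[2], W = d[3];
  t.set(N, C, H, W);
  const double* src = a.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const double* s = src + (size_t)N * (c + (size_t)C * (h + (size_t)H * w));
        for (int n = 0; n < N; ++n)
          t.v[((size_t)(n * C + c) * H + h) * W + w] = (T)s[n];
      }
}

template <typename T>
static NumericVector eng_to_r(const Tens<T>& t) {
  int N = t.n, C = t.c, H = t.h, W = t.w;
  NumericVector out((R_xlen_t)N * C * H * W);
  double* dst = out.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        double* d = dst + (size_t)N * (c + (size_t)C * (h + (size_t)H * w));
        for (int n = 0; n < N; ++n)
          d[n] = (double)t.v[((size_t)(n * C + c) * H + h) * W + w];
      }
  out.attr("dim") = IntegerVector::create(N, C, H, W);
  return out;
}

// conv weight (Co, Ci, KH, KW) R column-major -> GEMM matrix (Ci*KH*KW, Co)
// with row index (ci*KH + u)*KW + v, matching im2col row order.
template <typename T>
static arma::Mat<T> conv_wmat(const arma::Col<double>& flat,
                              const std::vector<int>& d) {
  int Co = d[0], Ci = d[1], KH = d[2], KW = d[3];
  arma::Mat<T> Wm(Ci * KH * KW, Co);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int u = 0; u < KH; ++u)
        for (int v = 0; v < KW; ++v)
          Wm((ci * KH + u) * KW + v, co) =
            (T)flat[co + (size_t)Co * (ci + (size_t)Ci * (u + (size_t)KH * v))];
  return Wm;
}

template <typename T>
static NumericVector wmat_to_r(const arma::Mat<T>& G, const std::vector<int>& d) {
  int Co = d[0], Ci = d[1], KH = d[2], KW = d[3];
  NumericVector out((R_xlen_t)Co * Ci * KH * KW);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int u = 0; u < KH; ++u)
        for (int v = 0; v < KW; ++v)
          out[co + (size_t)Co * (ci + (size_t)Ci * (u + (size_t)KH * v))] =
            (double)G((ci * KH + u) * KW + v, co);
  out.attr("dim") = IntegerVector::create(Co, Ci, KH, KW);
  return out;
}

// ---- cache --------------------------------------------------------------

struct CacheBase {
  virtual ~CacheBase() {}
  virtual List backward(List grads, IntegerVector gout_ids) = 0;
  virtual List forward_call(List params, List state, NumericVector x,
                            bool training, IntegerVector out_ids,
                            bool keep_aux) = 0;
  virtual void load_params(List params) = 0;
  virtual List forward_resident(List state, NumericVector x, bool training,
                                IntegerVector out_ids) = 0;
  virtual void backward_resident(List grads, IntegerVector gout_ids) = 0;
  virtual void sgd_step(double lr, double mu, double wd, LogicalVector decay,
                        double clip_norm) = 0;
  virtual List get_params() = 0;
};

template <typename T> struct Cache : CacheBase {
  std::vector<Instr> instrs;
  std::vector<Tens<T>> vals;
  // parameters live engine-resident in precision T: conv weights in GEMM
  // layout (Ci*KH*KW x Co), everything else flat in R order
  std::vector<arma::Col<T>> fparams;
  std::vector<arma::Mat<T>> wparams;
  std::vector<char> is_convw;
  std::vector<std::vector<int>> pdims;
  std::vector<arma::Col<double>> states;
  bool training = false;
  // per-instruction aux
  std::vector<arma::uvec> aux_idx;                  // gmp / chstat argmax
  std::vector<arma::Col<T>> bn_mean, bn_istd;
  std::vector<std::vector<arma::Mat<T>>> cols;      // im2col buffers
  std::vector<Tens<T>> gvals;                       // gradient buffers (reused)
  std::vector<arma::Col<T>> gflat;                  // parameter gradients
  std::vector<arma::Mat<T>> gw;                     //   (conv weights)
  std::vector<arma::Col<T>> vflat;                  // SGD momentum buffers
  std::vector<arma::Mat<T>> vw;

  void mark_conv_weights() {
    for (const Instr& I : instrs)
      if (I.op == OP_CONV) is_convw[I.p[0]] = 1;
  }
  List backward(List grads, IntegerVector gout_ids) override;
  void run_backward(List grads, IntegerVector gout_ids);
  void forward(const NumericVector& x, bool keep_aux);
  void set_params(List params_);
  void set_states(List state_);
  List forward_call(List params_, List state_, NumericVector x, bool training_,
                    IntegerVector out_ids, bool keep_aux) override;
  List collect_values(IntegerVector out_ids, List state_);
  void load_params(List params_) override { set_params(params_); }
  List forward_resident(List state_, NumericVector x, bool training_,
                        IntegerVector out_ids) override {
    training = training_;
    set_states(state_);
    forward(x, true);
    return collect_values(out_ids, state_);
  }
  void backward_resident(List grads, IntegerVector gout_ids) override {
    run_backward(grads, gout_ids);
  }
  void sgd_one(T* w, T* v, const T* gr, size_t n, T lr, T mu, T wd, T scale) {
    for (size_t t = 0; t < n; ++t) {
      T g = scale * gr[t] + wd * w[t];
      v[t] = mu * v[t] - lr * g;
      w[t] += v[t];
    }
  }
  void sgd_step(double lr, double mu, double wd, LogicalVector decay,
                double clip_norm) override {
    size_t np = pdims.size();
    if (vflat.size() != np) {
      vflat.resize(np); vw.resize(np);
      for (size_t i = 0; i < np; ++i) {
        if (is_convw[i]) vw[i].zeros(wparams[i].n_rows, wparams[i].n_cols);
        else vflat[i].zeros(fparams[i].n_elem);
      }
    }
    double scale = 1.0;
    if (clip_norm > 0) {
      double ss = 0;
      for (size_t i = 0; i < np; ++i)
        ss += is_convw[i] ? arma::accu(gw[i] % gw[i])
                          : arma::dot(gflat[i], gflat[i]);
      double nrm = std::sqrt(ss);
      if (nrm > clip_norm) scale = clip_norm / nrm;
    }
    for (size_t i = 0; i < np; ++i) {
      T wdi = decay[i] ? (T)wd : (T)0;
      if (is_convw[i])
        sgd_one(wparams[i].memptr(), vw[i].memptr(), gw[i].memptr(),
                wparams[i].n_elem, (T)lr, (T)mu, wdi, (T)scale);
      else
        sgd_one(fparams[i].memptr(), vflat[i].memptr(), gflat[i].memptr(),
                fparams[i].n_elem, (T)lr, (T)mu, wdi, (T)scale);
    }
  }
  List get_params() override {
    List out(pdims.size());
    for (size_t i = 0; i < pdims.size(); ++i) {
      if (is_convw[i]) {
        out[i] = wmat_to_r(wparams[i], pdims[i]);
      } else {
        NumericVector v(fparams[i].begin(), fparams[i].end());
        if (pdims[i].size() > 1)
          v.attr("dim") = IntegerVector(pdims[i].begin(), pdims[i].end());
        out[i] = v;
      }
    }
    return out;
  }
};

// ---- forward ops --------------------------------------------------------

template <typename T>
static void im2col(const Tens<T>& x, int n, int KH, int KW, int s, int p,
                   int d, int Ho, int Wo, arma::Mat<T>& col) {
  int Ci = x.c, H = x.h, W = x.w;
  col.zeros((arma::uword)Ho * Wo, (arma::uword)Ci * KH * KW);
  for (int ci = 0; ci < Ci; ++ci) {
    const T* plane = x.plane(n, ci);
    for (int u = 0; u < KH; ++u)
      for (int v = 0; v < KW; ++v) {
        T* dst = col.colptr((ci * KH + u) * KW + v);
        for (int oi = 0; oi < Ho; ++oi) {
          int ii = oi * s - p + u * d;
          if (ii < 0 || ii >= H) continue;
          const T* row = plane + (size_t)ii * W;
          T* drow = dst + (size_t)oi * Wo;
          for (int oj = 0; oj < Wo; ++oj) {
            int jj = oj * s - p + v * d;
            if (jj >= 0 && jj < W) drow[oj] = row[jj];
          }
        }
      }
  }
}

template <typename T>
static void col2im_add(const arma::Mat<T>& dcol, Tens<T>& dx, int n, int KH,
                       int KW, int s, int p, int d, int Ho, int Wo) {
  int Ci = dx.c, H = dx.h, W = dx.w;
  for (int ci = 0; ci < Ci; ++ci) {
    T* plane = dx.plane(n, ci);
    for (int u = 0; u < KH; ++u)
      for (int v = 0; v < KW; ++v) {
        const T* src = dcol.colptr((ci * KH + u) * KW + v);
        for (int oi = 0; oi < Ho; ++oi) {
          int ii = oi * s - p + u * d;
          if (ii < 0 || ii >= H) continue;
          T* row = plane + (size_t)ii * W;
          const T* srow = src + (size_t)oi * Wo;
          for (int oj = 0; oj < Wo; ++oj) {
            int jj = oj * s - p + v * d;
            if (jj >= 0 && jj < W) row[jj] += srow[oj];
          }
        }
      }
  }
}

template <typename T>
void Cache<T>::forward(const NumericVector& x, bool keep_aux) {
  size_t ni = instrs.size();
  aux_idx.assign(ni, arma::uvec());
  bn_mean.assign(ni, arma::Col<T>());
  bn_istd.assign(ni, arma::Col<T>());
  cols.assign(ni, std::vector<arma::Mat<T>>());
  r_to_eng(x, vals[0]);

  static double optime[16] = {0};
  bool prof = std::getenv("ENG_PROFILE") != nullptr;
  for (size_t q = 0; q < ni; ++q) {
    Instr& I = instrs[q];
    auto tic = std::chrono::steady_clock::now();
    switch (I.op) {
    case OP_CONV: {
      Tens<T>& X = vals[I.in[0]];
      const std::vector<int>& wd = pdims[I.p[0]];
      int Co = wd[0], KH = wd[2], KW = wd[3];
      int s = (int)I.k[0], p = (int)I.k[1], d = (int)I.k[2];
      bool bias = I.k[3] > 0.5;
      int Ho = (X.h + 2 * p - d * (KH - 1) - 1) / s + 1;
      int Wo = (X.w + 2 * p - d * (KW - 1) - 1) / s + 1;
      Tens<T>& O = vals[I.out];
      O.setraw(X.n, Co, Ho, Wo);
      const arma::Mat<T>& Wm = wparams[I.p[0]];
      bool one = (KH == 1 && KW == 1 && s == 1 && p == 0);
      if (keep_aux && !one) cols[q].resize(X.n);
      for (int n = 0; n < X.n; ++n) {
        arma::Mat<T> Ov(O.plane(n, 0), (arma::uword)Ho * Wo, Co, false, true);
        if (one) {
          arma::Mat<T> Xv(const_cast<T*>(X.plane(n, 0)),
                          (arma::uword)X.h * X.w, X.c, false, true);
          Ov = Xv * Wm;
        } else {
          arma::Mat<T> col;
          im2col(X, n, KH, KW, s, p, d, Ho, Wo, col);
          Ov = col * Wm;
          if (keep_aux) cols[q][n] = std::move(col);
        }
        if (bias) {
          const arma::Col<T>& b = fparams[I.p[1]];
          for (int co = 0; co < Co; ++co) Ov.col(co) += b[co];
        }
      }
      break;
    }
    case OP_DWCONV: {
      Tens<T>& X = vals[I.in[0]];
      const std::vector<int>& wd = pdims[I.p[0]];
      int C = wd[0], KH = wd[1], KW = wd[2];
      int s = (int)I.k[0], p = (int)I.k[1];
      int Ho = (X.h + 2 * p - KH) / s + 1, Wo = (X.w + 2 * p - KW) / s + 1;
      Tens<T>& O = vals[I.out];
      O.set(X.n, C, Ho, Wo);
      const arma::Col<T>& wf = fparams[I.p[0]];
      for (int n = 0; n < X.n; ++n)
        for (int c = 0; c < C; ++c) {
          const T* in = X.plane(n, c);
          T* out = O.plane(n, c);
          for (int u = 0; u < KH; ++u)
            for (int v = 0; v < KW; ++v) {
              T wv = (T)wf[c + (size_t)C * (u + (size_t)KH * v)];
              if (wv == (T)0) continue;
              for (int oi = 0; oi < Ho; ++oi) {
                int ii = oi * s - p + u;
                if (ii < 0 || ii >= X.h) continue;
                const T* row = in + (size_t)ii * X.w;
                T* orow = out + (size_t)oi * Wo;
                if (s == 1) {
                  int oj0 = std::max(0, p - v), oj1 = std::min(Wo, X.w + p - v);
                  if (oj1 > oj0)
                    k_axpy(orow + oj0, row + (oj0 - p + v), wv, oj1 - oj0);
                } else {
                  for (int oj = 0; oj < Wo; ++oj) {
                    int jj = oj * s - p + v;
                    if (jj >= 0 && jj < X.w) orow[oj] += wv * row[jj];
                  }
                }
              }
            }
        }
      break;
    }
    case OP_BN: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& O = vals[I.out];
      O.setraw(X.n, X.c, X.h, X.w);
      double eps = I.k[0], mom = I.k[1];
      const arma::Col<T>& gam = fparams[I.p[0]];
      const arma::Col<T>& bet = fparams[I.p[1]];
      arma::Col<double>& rm = states[I.s[0]];
      arma::Col<double>& rv = states[I.s[1]];
      size_t psz = X.plane_sz();
      double cnt = (double)X.n * psz;
      arma::Col<T> mean(X.c), istd(X.c);
      for (int c = 0; c < X.c; ++c) {
        double m, var;
        if (training) {
          double acc = 0, acc2 = 0;
          for (int n = 0; n < X.n; ++n)
            k_bnstats(X.plane(n, c), psz, acc, acc2);
          m = acc / cnt;
          var = acc2 / cnt - m * m;
          if (var < 0) var = 0;
          rm[c] = (1 - mom) * rm[c] + mom * m;
          rv[c] = (1 - mom) * rv[c] + mom * var * cnt / std::max(cnt - 1.0, 1.0);
        } else {
          m = rm[c]; var = rv[c];
        }
        double is = 1.0 / std::sqrt(var + eps);
        mean[c] = (T)m; istd[c] = (T)is;
        T a = (T)(gam[c] * is), b = (T)(bet[c] - gam[c] * is * m);
        for (int n = 0; n < X.n; ++n)
          k_axpb(X.plane(n, c), O.plane(n, c), psz, a, b);
      }
      if (keep_aux) { bn_mean[q] = mean; bn_istd[q] = istd; }
      break;
    }
    case OP_RELU: case OP_SILU: case OP_SIGMOID: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& O = vals[I.out];
      O.setraw(X.n, X.c, X.h, X.w);
      size_t m = X.v.n_elem;
      const T* xi = X.v.memptr(); T* oo = O.v.memptr();
      if (I.op == OP_RELU) k_relu(xi, oo, m);
      else if (I.op == OP_SILU) k_silu(xi, oo, m);
      else k_sigm(xi, oo, m);
      break;
    }
    case OP_GAP: case OP_GMP: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& O = vals[I.out];
      O.setraw(X.n, X.c, 1, 1);
      size_t psz = X.plane_sz();
      if (I.op == OP_GMP && keep_aux) aux_idx[q].set_size((size_t)X.n * X.c);
      for (int n = 0; n < X.n; ++n)
        for (int c = 0; c < X.c; ++c) {
          const T* pl = X.plane(n, c);
          if (I.op == OP_GAP) {
            double acc = 0;
            for (size_t t = 0; t < psz; ++t) acc += pl[t];
            O.v[(size_t)n * X.c + c] = (T)(acc / psz);
          } else {
            size_t bi = 0; T bv = pl[0];
            for (size_t t = 1; t < psz; ++t) if (pl[t] > bv) { bv = pl[t]; bi = t; }
            O.v[(size_t)n * X.c + c] = bv;
            if (keep_aux) aux_idx[q][(size_t)n * X.c + c] = bi;
          }
        }
      break;
    }
    case OP_MUL: {
      Tens<T>& A = vals[I.in[0]];
      Tens<T>& B = vals[I.in[1]];
      Tens<T>& O = vals[I.out];
      O.setraw(A.n, A.c, A.h, A.w);
      size_t psz = A.plane_sz();
      if (B.c == A.c && B.h == A.h && B.w == A.w) {
        O.v = A.v % B.v;
      } else if (B.h == 1 && B.w == 1) {        // channel gate (N,C,1,1)
        for (int n = 0; n < A.n; ++n)
          for (int c = 0; c < A.c; ++c)
            k_scale(A.plane(n, c), O.plane(n, c),
                    B.v[(size_t)n * A.c + c], psz);
      } else if (B.c == 1) {                    // spatial gate (N,1,H,W)
        for (int n = 0; n < A.n; ++n) {
          const T* pg = B.plane(n, 0);
          for (int c = 0; c < A.c; ++c) {
            const T* pa = A.plane(n, c); T* po = O.plane(n, c);
            for (size_t t = 0; t < psz; ++t) po[t] = pg[t] * pa[t];
          }
        }
      } else stop("mul: unsupported broadcast");
      break;
    }
    case OP_ADD: {
      Tens<T>& A = vals[I.in[0]];
      Tens<T>& B = vals[I.in[1]];
      Tens<T>& O = vals[I.out];
      O.setraw(A.n, A.c, A.h, A.w);
      O.v = A.v + B.v;
      break;
    }
    case OP_CHSTAT: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& O = vals[I.out];
      O.setraw(X.n, 2, X.h, X.w);
      size_t psz = X.plane_sz();
      if (keep_aux) aux_idx[q].set_size((size_t)X.n * psz);
      for (int n = 0; n < X.n; ++n) {
        T* pavg = O.plane(n, 0);
        T* pmax = O.plane(n, 1);
        for (size_t t = 0; t < psz; ++t) {
          double acc = 0; T bv = X.plane(n, 0)[t]; int bc = 0;
          for (int c = 0; c < X.c; ++c) {
            T v = X.plane(n, c)[t];
            acc += v;
            if (v > bv) { bv = v; bc = c; }
          }
          pavg[t] = (T)(acc / X.c);
          pmax[t] = bv;
          if (keep_aux) aux_idx[q][(size_t)n * psz + t] = bc;
        }
      }
      break;
    }
    case OP_CONV1DCH: {
      Tens<T>& X = vals[I.in[0]];
      const arma::Col<T>& wf = fparams[I.p[0]];
      int K = (int)wf.n_elem, pad = (K - 1) / 2, C = X.c;
      Tens<T>& O = vals[I.out];
      O.set(X.n, C, 1, 1);
      for (int n = 0; n < X.n; ++n)
        for (int c = 0; c < C; ++c) {
          double acc = 0;
          for (int u = 0; u < K; ++u) {
            int cc = c + u - pad;
            if (cc >= 0 && cc < C) acc += wf[u] * X.v[(size_t)n * C + cc];
          }
          O.v[(size_t)n * C + c] = (T)acc;
        }
      break;
    }
    default: stop("forward: bad op");
    }
    if (prof) {
      optime[I.op] += std::chrono::duration<double>(
        std::chrono::steady_clock::now() - tic).count();
      if (q == ni - 1)
        for (int o = 0; o < 12; ++o) Rprintf("fwd op %d: %.3f s\n", o, optime[o]);
    }
  }
}

// ---- backward -----------------------------------------------------------

template <typename T>
List Cache<T>::backward(List grads, IntegerVector gout_ids) {
  run_backward(grads, gout_ids);
  List out(pdims.size());
  for (size_t i = 0; i < pdims.size(); ++i) {
    if (is_convw[i]) {
      out[i] = wmat_to_r(gw[i], pdims[i]);
    } else {
      NumericVector v(gflat[i].begin(), gflat[i].end());
      const std::vector<int>& d = pdims[i];
      if (d.size() > 1) v.attr("dim") = IntegerVector(d.begin(), d.end());
      out[i] = v;
    }
  }
  return out;
}

template <typename T>
void Cache<T>::run_backward(List grads, IntegerVector gout_ids) {
  size_t ni = instrs.size();
  std::vector<Tens<T>>& g = gvals;
  g.resize(vals.size());
  for (size_t i = 0; i < g.size(); ++i) g[i].alloc = false;
  for (int i = 0; i < gout_ids.size(); ++i) {
    int id = gout_ids[i] - 1;
    Tens<T> gt;
    r_to_eng(as<NumericVector>(grads[i]), gt);
    if (!g[id].alloc) g[id].set(gt.n, gt.c, gt.h, gt.w);
    g[id].v += gt.v;
  }
  std::vector<arma::Col<T>>& pg = gflat;
  pg.resize(pdims.size());
  gw.resize(pdims.size());
  for (size_t i = 0; i < pdims.size(); ++i) {
    if (is_convw[i]) gw[i].zeros(wparams[i].n_rows, wparams[i].n_cols);
    else pg[i].zeros(fparams[i].n_elem);
  }

  auto need = [&](int id, const Tens<T>& like) -> Tens<T>& {
    if (!g[id].alloc) g[id].set(like.n, like.c, like.h, like.w);
    return g[id];
  };

  static double optimeb[16] = {0};
  bool prof = std::getenv("ENG_PROFILE") != nullptr;
  for (size_t qq = ni; qq-- > 0;) {
    Instr& I = instrs[qq];
    if (!g[I.out].alloc) continue;
    Tens<T>& G = g[I.out];
    auto tic = std::chrono::steady_clock::now();
    switch (I.op) {
    case OP_CONV: {
      Tens<T>& X = vals[I.in[0]];
      const std::vector<int>& wd = pdims[I.p[0]];
      int Co = wd[0], KH = wd[2], KW = wd[3];
      int s = (int)I.k[0], p = (int)I.k[1], d = (int)I.k[2];
      bool bias = I.k[3] > 0.5;
      int Ho = G.h, Wo = G.w;
      const arma::Mat<T>& Wm = wparams[I.p[0]];
      arma::Mat<T>& dWm = gw[I.p[0]];
      arma::Col<T> db(Co, arma::fill::zeros);
      Tens<T>& dX = need(I.in[0], X);
      bool one = (KH == 1 && KW == 1 && s == 1 && p == 0);
      for (int n = 0; n < X.n; ++n) {
        arma::Mat<T> Gv(G.plane(n, 0), (arma::uword)Ho * Wo, Co, false, true);
        if (one) {
          arma::Mat<T> Xv(X.plane(n, 0), (arma::uword)X.h * X.w, X.c, false, true);
          dWm += Xv.t() * Gv;
          arma::Mat<T> dXv(dX.plane(n, 0), (arma::uword)X.h * X.w, X.c, false, true);
          dXv += Gv * Wm.t();
        } else {
          arma::Mat<T>& col = cols[qq][n];
          dWm += col.t() * Gv;
          arma::Mat<T> dcol = Gv * Wm.t();
          col2im_add(dcol, dX, n, KH, KW, s, p, d, Ho, Wo);
        }
        if (bias) db += arma::sum(Gv, 0).t();
      }
      if (bias)
        for (int co = 0; co < Co; ++co) pg[I.p[1]][co] += db[co];
      break;
    }
    case OP_DWCONV: {
      Tens<T>& X = vals[I.in[0]];
      const std::vector<int>& wd = pdims[I.p[0]];
      int C = wd[0], KH = wd[1], KW = wd[2];
      int s = (int)I.k[0], p = (int)I.k[1];
      int Ho = G.h, Wo = G.w;
      const arma::Col<T>& wf = fparams[I.p[0]];
      Tens<T>& dX = need(I.in[0], X);
      for (int n = 0; n < X.n; ++n)
        for (int c = 0; c < C; ++c) {
          const T* in = X.plane(n, c);
          const T* go = G.plane(n, c);
          T* din = dX.plane(n, c);
          for (int u = 0; u < KH; ++u)
            for (int v = 0; v < KW; ++v) {
              T wv = (T)wf[c + (size_t)C * (u + (size_t)KH * v)];
              double dw = 0;
              for (int oi = 0; oi < Ho; ++oi) {
                int ii = oi * s - p + u;
                if (ii < 0 || ii >= X.h) continue;
                const T* row = in + (size_t)ii * X.w;
                T* drow = din + (size_t)ii * X.w;
                const T* grow = go + (size_t)oi * Wo;
                if (s == 1) {
                  int oj0 = (p - v > 0) ? p - v : 0;
                  int oj1 = (Wo < X.w + p - v) ? Wo : X.w + p - v;
                  if (oj1 > oj0)
                    dw += k_dotaxpy(drow + (oj0 - p + v), row + (oj0 - p + v),
                                    grow + oj0, wv, oj1 - oj0);
                } else {
                  T acc = 0;
                  for (int oj = 0; oj < Wo; ++oj) {
                    int jj = oj * s - p + v;
                    if (jj < 0 || jj >= X.w) continue;
                    acc += grow[oj] * row[jj];
                    drow[jj] += wv * grow[oj];
                  }
                  dw += acc;
                }
              }
              pg[I.p[0]][c + (size_t)C * (u + (size_t)KH * v)] += (T)dw;
            }
        }
      break;
    }
    case OP_BN: {
      Tens<T>& X = vals[I.in[0]];
      const arma::Col<T>& gam = fparams[I.p[0]];
      Tens<T>& dX = need(I.in[0], X);
      size_t psz = X.plane_sz();
      double cnt = (double)X.n * psz;
      for (int c = 0; c < X.c; ++c) {
        T m = bn_mean[qq][c], is = bn_istd[qq][c];
        double dg = 0, dbta = 0;
        for (int n = 0; n < X.n; ++n)
          k_bnred(X.plane(n, c), G.plane(n, c), psz, m, is, dg, dbta);
        pg[I.p[0]][c] += (T)dg;
        pg[I.p[1]][c] += (T)dbta;
        double a = (double)gam[c] * is;
        if (training) {
          T ta = (T)a, c1 = (T)(a * dbta / cnt), c2 = (T)(a * dg / cnt);
          for (int n = 0; n < X.n; ++n)
            k_bndx(X.plane(n, c), G.plane(n, c), dX.plane(n, c), psz, m, is,
                   ta, c1, c2);
        } else {
          for (int n = 0; n < X.n; ++n) {
            const T* pgd = G.plane(n, c);
            T* pdx = dX.plane(n, c);
            for (size_t t = 0; t < psz; ++t) pdx[t] += (T)(a * pgd[t]);
          }
        }
      }
      break;
    }
    case OP_RELU: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& dX = need(I.in[0], X);
      k_relu_b(X.v.memptr(), G.v.memptr(), dX.v.memptr(), X.v.n_elem);
      break;
    }
    case OP_SILU: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& dX = need(I.in[0], X);
      k_silu_b(X.v.memptr(), G.v.memptr(), dX.v.memptr(), X.v.n_elem);
      break;
    }
    case OP_SIGMOID: {
      Tens<T>& O = vals[I.out];
      Tens<T>& dX = need(I.in[0], vals[I.in[0]]);
      k_sigm_b(O.v.memptr(), G.v.memptr(), dX.v.memptr(), O.v.n_elem);
      break;
    }
    case OP_GAP: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& dX = need(I.in[0], X);
      size_t psz = X.plane_sz();
      for (int n = 0; n < X.n; ++n)
        for (int c = 0; c < X.c; ++c) {
          T gv = (T)(G.v[(size_t)n * X.c + c] / (T)psz);
          T* pdx = dX.plane(n, c);
          for (size_t t = 0; t < psz; ++t) pdx[t] += gv;
        }
      break;
    }
    case OP_GMP: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& dX = need(I.in[0], X);
      for (int n = 0; n < X.n; ++n)
        for (int c = 0; c < X.c; ++c)
          dX.plane(n, c)[aux_idx[qq][(size_t)n * X.c + c]] +=
            G.v[(size_t)n * X.c + c];
      break;
    }
    case OP_MUL: {
      Tens<T>& A = vals[I.in[0]];
      Tens<T>& B = vals[I.in[1]];
      Tens<T>& dA = need(I.in[0], A);
      Tens<T>& dB = need(I.in[1], B);
      size_t psz = A.plane_sz();
      if (B.c == A.c && B.h == A.h && B.w == A.w) {
        dA.v += G.v % B.v;
        dB.v += G.v % A.v;
      } else if (B.h == 1 && B.w == 1) {
        for (int n = 0; n < A.n; ++n)
          for (int c = 0; c < A.c; ++c)
            dB.v[(size_t)n * A.c + c] +=
              k_scale_dot(A.plane(n, c), G.plane(n, c), dA.plane(n, c),
                          B.v[(size_t)n * A.c + c], psz);
      } else {
        for (int n = 0; n < A.n; ++n) {
          const T* pgate = B.plane(n, 0);
          T* pdb = dB.plane(n, 0);
          for (int c = 0; c < A.c; ++c) {
            const T* pa = A.plane(n, c); const T* pgd = G.plane(n, c);
            T* pda = dA.plane(n, c);
            for (size_t t = 0; t < psz; ++t) {
              pda[t] += pgate[t] * pgd[t];
              pdb[t] += pa[t] * pgd[t];
            }
          }
        }
      }
      break;
    }
    case OP_ADD: {
      Tens<T>& dA = need(I.in[0], vals[I.in[0]]);
      Tens<T>& dB = need(I.in[1], vals[I.in[1]]);
      dA.v += G.v;
      dB.v += G.v;
      break;
    }
    case OP_CHSTAT: {
      Tens<T>& X = vals[I.in[0]];
      Tens<T>& dX = need(I.in[0], X);
      size_t psz = X.plane_sz();
      for (int n = 0; n < X.n; ++n) {
        const T* g0 = G.plane(n, 0);
        const T* g1 = G.plane(n, 1);
        for (size_t t = 0; t < psz; ++t) {
          T gm = (T)(g0[t] / (T)X.c);
          for (int c = 0; c < X.c; ++c) dX.plane(n, c)[t] += gm;
          dX.plane(n, (int)aux_idx[qq][(size_t)n * psz + t])[t] += g1[t];
        }
      }
      break;
    }
    case OP_CONV1DCH: {
      Tens<T>& X = vals[I.in[0]];
      const arma::Col<T>& wf = fparams[I.p[0]];
      int K = (int)wf.n_elem, pad = (K - 1) / 2, C = X.c;
      Tens<T>& dX = need(I.in[0], X);
      for (int n = 0; n < X.n; ++n)
        for (int c = 0; c < C; ++c) {
          double gv = (double)G.v[(size_t)n * C + c];
          for (int u = 0; u < K; ++u) {
            int cc = c + u - pad;
            if (cc >= 0 && cc < C) {
              dX.v[(size_t)n * C + cc] += (T)((double)wf[u] * gv);
              pg[I.p[0]][u] += (T)(gv * (double)X.v[(size_t)n * C + cc]);
            }
          }
        }
      break;
    }
    default: stop("backward: bad op");
    }
    if (prof) {
      optimeb[I.op] += std::chrono::duration<double>(
        std::chrono::steady_clock::now() - tic).count();
      if (qq == 0)
        for (int o = 0; o < 12; ++o) Rprintf("bwd op %d: %.3f s\n", o, optimeb[o]);
    }
  }

}

// ---- entry points -------------------------------------------------------

static void parse_instrs(List instrs, std::vector<Instr>& out, int& nvals) {
  nvals = 1;
  for (int i = 0; i < instrs.size(); ++i) {
    List L = instrs[i];
    Instr I;
    I.op = op_code(as<std::string>(L["op"]));
    IntegerVector iv = L["in"];
    for (int j = 0; j < iv.size(); ++j) I.in.push_back(iv[j] - 1);
    I.out = as<int>(L["out"]) - 1;
    if (L.containsElementNamed("p") && !Rf_isNull(L["p"])) {
      IntegerVector pv = L["p"];
      for (int j = 0; j < pv.size(); ++j) I.p.push_back(pv[j] - 1);
    }
    if (L.containsElementNamed("s") && !Rf_isNull(L["s"])) {
      IntegerVector sv = L["s"];
      for (int j = 0; j < sv.size(); ++j) I.s.push_back(sv[j] - 1);
    }
    if (L.containsElementNamed("k") && !Rf_isNull(L["k"])) {
      NumericVector kv = L["k"];
      for (int j = 0; j < kv.size(); ++j) I.k.push_back(kv[j]);
    }
    nvals = std::max(nvals, I.out + 1);
    out.push_back(I);
  }
}

template <typename T>
void Cache<T>::set_params(List params_) {
  fparams.resize(params_.size());
  wparams.resize(params_.size());
  is_convw.assign(params_.size(), 0);
  pdims.resize(params_.size());
  for (int i = 0; i < params_.size(); ++i) {
    NumericVector a = params_[i];
    SEXP dm = a.attr("dim");
    if (!Rf_isNull(dm)) {
      IntegerVector d(dm);
      pdims[i] = std::vector<int>(d.begin(), d.end());
    } else pdims[i] = { (int)a.size() };
  }
  mark_conv_weights();
  for (int i = 0; i < params_.size(); ++i) {
    NumericVector a = params_[i];
    arma::Col<double> flat(a.begin(), a.size());
    if (is_convw[i]) wparams[i] = conv_wmat<T>(flat, pdims[i]);
    else {
      fparams[i].set_size(a.size());
      for (R_xlen_t t = 0; t < a.size(); ++t) fparams[i][t] = (T)a[t];
    }
  }
}

template <typename T>
void Cache<T>::set_states(List state_) {
  states.resize(state_.size());
  for (int i = 0; i < state_.size(); ++i) {
    NumericVector a = state_[i];
    states[i] = arma::Col<double>(a.begin(), a.size());
  }
}

template <typename T>
List Cache<T>::forward_call(List params_, List state_, NumericVector x,
                            bool training_, IntegerVector out_ids,
                            bool keep_aux) {
  training = training_;
  set_params(params_);
  set_states(state_);
  forward(x, keep_aux);
  return collect_values(out_ids, state_);
}

template <typename T>
List Cache<T>::collect_values(IntegerVector out_ids, List state_) {
  List vals_out(out_ids.size());
  for (int i = 0; i < out_ids.size(); ++i)
    vals_out[i] = eng_to_r(vals[out_ids[i] - 1]);
  List st_out(state_.size());
  for (int i = 0; i < (int)states.size(); ++i)
    st_out[i] = NumericVector(states[i].begin(), states[i].end());
  st_out.attr("names") = state_.attr("names");
  return List::create(Named("values") = vals_out, Named("state") = st_out);
}

static CacheBase* make_cache(List instrs, bool use_double) {
  std::vector<Instr> iv;
  int nvals = 0;
  parse_instrs(instrs, iv, nvals);
  if (use_double) {
    Cache<double>* C = new Cache<double>();
    C->instrs = iv; C->vals.resize(nvals);
    return C;
  }
  Cache<float>* C = new Cache<float>();
  C->instrs = iv; C->vals.resize(nvals);
  return C;
}

// one-shot forward (optionally returning the autodiff cache)
// [[Rcpp::export]]
SEXP eng_forward(List instrs, List params, List state, NumericVector x,
                 bool training, IntegerVector out_ids, bool keep_cache,
                 bool use_double) {
  CacheBase* C = make_cache(instrs, use_double);
  List res = C->forward_call(params, state, x, training, out_ids, keep_cache);
  if (keep_cache) {
    XPtr<CacheBase> xp(C, true);
    res["cache"] = xp;
  } else delete C;
  return res;
}

// persistent context: buffers are reused across iterations
// [[Rcpp::export]]
SEXP eng_ctx(List instrs, bool use_double) {
  return XPtr<CacheBase>(make_cache(instrs, use_double), true);
}

// [[Rcpp::export]]
List eng_ctx_forward(SEXP ctx, List params, List state, NumericVector x,
                     bool training, IntegerVector out_ids) {
  XPtr<CacheBase> xp(ctx);
  return xp->forward_call(params, state, x, training, out_ids, true);
}

// [[Rcpp::export]]
List eng_backward(SEXP cache, List grads, IntegerVector gout_ids) {
  XPtr<CacheBase> xp(cache);
  return xp->backward(grads, gout_ids);
}

// resident-parameter training API: weights, gradients and momentum live in
// the context; R drives iterations and supplies only head-output gradients
// [[Rcpp::export]]
void eng_ctx_load_params(SEXP ctx, List params) {
  XPtr<CacheBase>(ctx)->load_params(params);
}

// [[Rcpp::export]]
List eng_ctx_forward_res(SEXP ctx, List state, NumericVector x, bool training,
                         IntegerVector out_ids) {
  return XPtr<CacheBase>(ctx)->forward_resident(state, x, training, out_ids);
}

// [[Rcpp::export]]
void eng_ctx_backward_res(SEXP ctx, List grads, IntegerVector gout_ids) {
  XPtr<CacheBase>(ctx)->backward_resident(grads, gout_ids);
}

// [[Rcpp::export]]
void eng_ctx_sgd(SEXP ctx, double lr, double momentum, double weight_decay,
                 LogicalVector decay, double clip_norm) {
  XPtr<CacheBase>(ctx)->sgd_step(lr, momentum, weight_decay, decay, clip_norm);
}

// [[Rcpp::export]]
List eng_ctx_params(SEXP ctx) {
  return XPtr<CacheBase>(ctx)->get_params();
}

// [[Rcpp::export]]
void eng_free(SEXP cache) {
  CacheBase* p = (CacheBase*)R_ExternalPtrAddr(cache);
  if (p) { delete p; R_ClearExternalPtr(cache); }
}
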