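// Convolutional ERP encoder: forward and backward passes.
//
// Block 1: three parallel temporal convolutions (shared across EEG channels),
//          squeeze-and-excitation over the map axis, depthwise spatial
//          convolution over all channels, batch norm, ELU, average pool,
//          dropout.
// Block 2: depthwise temporal convolution, efficient channel attention in
//          place of a pointwise convolution, batch norm, ELU, average pool,
//          dropout.
// Head:    flatten -> linear map to 1024 -> batch norm (no activation).
//
// Layout: the input cube is (T samples, C channels, N trials); internally a
// map's activations live in a (T x N) matrix, and the pre-spatial stage in a
// (T x C*N) matrix whose column c + C*n is channel c of trial n.
// Gradients are computed analytically (verified against finite differences
// in the test suite), including the batch-statistics terms of batch norm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Saturated activations underflow to subnormal doubles, which x86 handles
// in microcode at a ~100x penalty; flush them to zero (they are far below
// any numerically meaningful scale here).
#if defined(__SSE3__) || defined(__x86_64__)
#include <pmmintrin.h>
static inline void flush_denormals() {
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
}
#else
static inline void flush_denormals() {}
#endif

// The per-step working set is a few hundred MB of short-lived buffers; keep
// glibc from handing them back to the kernel after every free (mmap/munmap
// churn re-pays page faults on every training step).
#if defined(__GLIBC__)
#include <malloc.h>
static bool malloc_tuned = []() {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  return true;
}();
#endif

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct EncCache {
  int T, C, N, F1, B, M1, M2, DM, T1, T2, pool1, pool2;
  bool use_se, use_eca, training, frozen;
  double dropout;
  mat S;                 // input view (T, C*N)
  mat patches;           // shared im2col matrix (T*C*N, Kmax)
  field<mat> A1;         // raw temporal-conv maps, M1 x (T, C*N)
  mat Ssq, H1, Gse;      // squeeze-and-excitation internals
  field<mat> xhat1;      // BN1 normalized activations, M2 x (T, N)
  vec invstd1;
  field<mat> elu1;       // post-ELU, M2 x (T, N)
  field<mat> mask1;      // dropout masks, M2 x (T1, N)
  field<mat> X1;         // block-2 input, M2 x (T1, N)
  field<mat> U;          // raw depthwise temporal conv, M2 x (T1, N)
  mat D, Geca;           // ECA descriptors and gates (M2, N)
  field<mat> xhat2;
  vec invstd2;
  field<mat> elu2;
  field<mat> mask2;      // M2 x (T2, N)
  mat Fl;                // flattened (M2*T2, N)
  mat xhat3;             // BN3 normalized (1024, N)
  vec invstd3;
};

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
static inline mat elu(const mat& x) {
  mat y = x;
  uvec neg = find(x < 0);
  y(neg) = exp(x(neg)) - 1.0;
  return y;
}
// ELU gradient expressed through the cached output (y + 1 = exp(x) for x < 0).
static inline mat elu_backward(const mat& dy, const mat& y) {
  mat dx = dy;
  uvec neg = find(y < 0);
  dx(neg) = dy(neg) % (y(neg) + 1.0);
  return dx;
}

static mat dropout_mask(int rows, int cols, double p, std::mt19937_64& rng) {
  mat m(rows, cols);
  const double keep = 1.0 - p;
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) {
      double u = ((rng() >> 11) * (1.0 / 9007199254740992.0));
      m(i, j) = (u < keep) ? 1.0 / keep : 0.0;
    }
  return m;
}

static mat avgpool(const mat& x, int p) {
  int T1 = x.n_rows / p;
  mat y(T1, x.n_cols, fill::zeros);
  for (int t = 0; t < T1; ++t)
    for (int u = 0; u < p; ++u) y.row(t) += x.row(t * p + u);
  return y / p;
}

static mat avgpool_backward(const mat& dy, int p, int T) {
  mat dx(T, dy.n_cols, fill::zeros);
  int T1 = dy.n_rows;
  for (int t = 0; t < T1; ++t)
    for (int u = 0; u < p; ++u) dx.row(t * p + u) = dy.row(t) / p;
  return dx;
}

// Batch norm over all elements of a (T x N) map (one gamma/beta per map).
// Statistics come from the batch itself (training), from the running
// buffers (evaluation), or from a caller-supplied frozen source (a query
// batch normalized in the frame of its episode's support batch); only
// batch-own statistics update the running buffers. `stat_m`/`stat_v`
// record the statistics actually used.
static mat bn_map_forward(const mat& x, double gamma, double beta, bool training,
                          bool frozen, double fix_m, double fix_v,
                          double& run_m, double& run_v, mat& xhat, double& invstd,
                          double& stat_m, double& stat_v) {
  double mu, v;
  if (frozen) {
    mu = fix_m; v = fix_v;
  } else if (training) {
    mu = accu(x) / x.n_elem;
    v = accu(square(x - mu)) / x.n_elem;
    run_m = (1 - BN_MOMENTUM) * run_m + BN_MOMENTUM * mu;
    run_v = (1 - BN_MOMENTUM) * run_v + BN_MOMENTUM * v;
  } else {
    mu = run_m; v = run_v;
  }
  stat_m = mu; stat_v = v;
  invstd = 1.0 / std::sqrt(v + BN_EPS);
  xhat = (x - mu) * invstd;
  return gamma * xhat + beta;
}

// `batch_stats = false` (frozen statistics) drops the mean/variance terms,
// as the statistics are constants with respect to this batch.
static mat bn_map_backward(const mat& dy, const mat& xhat, double invstd,
                           double gamma, bool batch_stats,
                           double& dgamma, double& dbeta) {
  dgamma = accu(dy % xhat);
  dbeta = accu(dy);
  if (!batch_stats) return gamma * invstd * dy;
  double n = dy.n_elem;
  mat dxhat = gamma * dy;
  double m1 = accu(dxhat) / n;
  double m2 = accu(dxhat % xhat) / n;
  return invstd * (dxhat - m1 - xhat * m2);
}

// [[Rcpp::export(name = ".enc_forward")]]
List enc_forward(List params, const arma::cube& X, List hyper, bool training,
                 bool want_cache, double seed,
                 Nullable<List> fixed_stats = R_NilValue) {
  flush_denormals();
  EncCache* cc = new EncCache();
  EncCache& c = *cc;
  XPtr<EncCache> cache(cc, true);

  c.T = X.n_rows; c.C = X.n_cols; c.N = X.n_slices;
  c.pool1 = as<int>(hyper["pool1"]);
  c.pool2 = as<int>(hyper["pool2"]);
  c.use_se = as<bool>(hyper["use_se"]);
  c.use_eca = as<bool>(hyper["use_eca"]);
  c.dropout = training ? as<double>(hyper["dropout"]) : 0.0;
  c.training = training;
  c.frozen = fixed_stats.isNotNull();
  vec fx_m1, fx_v1, fx_m2, fx_v2, fx_m3, fx_v3;
  if (c.frozen) {
    List fs(fixed_stats);
    fx_m1 = as<vec>(fs["bn1_m"]); fx_v1 = as<vec>(fs["bn1_v"]);
    fx_m2 = as<vec>(fs["bn2_m"]); fx_v2 = as<vec>(fs["bn2_v"]);
    fx_m3 = as<vec>(fs["bn3_m"]); fx_v3 = as<vec>(fs["bn3_v"]);
  }

  List wt = params["wt"];
  c.B = wt.size();
  mat w0 = as<mat>(wt[0]);
  c.F1 = w0.n_cols;
  c.M1 = c.B * c.F1;
  cube wsp = as<cube>(params["wsp"]);          // (C, DM, M1)
  c.DM = wsp.n_cols;
  c.M2 = c.M1 * c.DM;
  c.T1 = c.T / c.pool1;
  c.T2 = c.T1 / c.pool2;
  if (c.T1 < 1 || c.T2 < 1) stop("pooling reduces the epoch to zero samples");

  std::mt19937_64 rng((unsigned long long) seed);
  const int T = c.T, C = c.C, N = c.N, CN = C * N;

  c.S = mat(const_cast<double*>(X.memptr()), T, CN, true, false);

  // --- Block 1: multiscale temporal convolution (same padding, zero pad) ---
  // One shared im2col patch matrix serves all branches: its column for
  // shift s holds the signal shifted by s, and a branch with K taps uses
  // the K centered columns, so  A1_branch = patches_view * W  is one GEMM.
  // The patch matrix is kept in the cache for the backward kernel GEMMs.
  c.A1.set_size(c.M1);
  {
    int Kmax = 0;
    for (int b = 0; b < c.B; ++b)
      Kmax = std::max(Kmax, (int)as<mat>(wt[b]).n_rows);
    int Pmax = (Kmax - 1) / 2;
    c.patches = mat(T * CN, Kmax, fill::zeros);
    const double* sp = c.S.memptr();
    for (int k = 0; k < Kmax; ++k) {
      int sh = k - Pmax;
      int t0 = std::max(0, -sh), t1 = std::min(T - 1, T - 1 - sh);
      if (t0 > t1) continue;
      double* pk = c.patches.colptr(k);
      for (int col = 0; col < CN; ++col)
        std::copy(sp + col * T + t0 + sh, sp + col * T + t1 + sh + 1,
                  pk + col * T + t0);
    }
    for (int b = 0; b < c.B; ++b) {
      mat W = as<mat>(wt[b]);                  // (K, F1)
      int K = W.n_rows, o = Pmax - (K - 1) / 2;
      mat out = c.patches.cols(o, o + K - 1) * W;   // (T*CN, F1)
      for (int f = 0; f < c.F1; ++f)
        c.A1(b * c.F1 + f) = reshape(out.col(f), T, CN);
    }
  }

  // --- Squeeze-and-excitation over the M1 maps (per trial) ---
  c.Gse = mat(c.M1, N, fill::ones);
  if (c.use_se) {
    c.Ssq = mat(c.M1, N);
    for (int m = 0; m < c.M1; ++m) {
      // (T, C*N) shares its memory layout with (T*C, N): column = trial
      mat Av(c.A1(m).memptr(), (uword)(T * C), (uword)N, false, true);
      c.Ssq.row(m) = sum(Av, 0) / (double)(T * C);
    }
    mat se_w1 = as<mat>(params["se_w1"]);      // (M1, H)
    vec se_b1 = as<vec>(params["se_b1"]);
    mat se_w2 = as<mat>(params["se_w2"]);      // (H, M1)
    vec se_b2 = as<vec>(params["se_b2"]);
    mat L1 = se_w1.t() * c.Ssq;
    L1.each_col() += se_b1;
    c.H1 = clamp(L1, 0.0, datum::inf);         // ReLU
    mat L2 = se_w2.t() * c.H1;
    L2.each_col() += se_b2;
    c.Gse = sigmoid(L2);
  }

  // --- Depthwise spatial convolution over all channels ---
  field<mat> Z(c.M2);
  for (int m = 0; m < c.M1; ++m) {
    mat W = wsp.slice(m);                      // (C, DM)
    mat Av(c.A1(m).memptr(), (uword)(T * C), (uword)N, false, true);
    for (int j = 0; j < c.DM; ++j) {
      mat Zr(T, N, fill::zeros);
      for (int ch = 0; ch < C; ++ch)
        Zr += W(ch, j) * Av.rows(T * ch, T * ch + T - 1);
      if (c.use_se) Zr.each_row() %= c.Gse.row(m);
      Z(m * c.DM + j) = std::move(Zr);
    }
  }

  // --- BN1, ELU, pool, dropout ---
  vec g1 = as<vec>(params["bn1_gamma"]), b1 = as<vec>(params["bn1_beta"]);
  vec rm1 = as<vec>(params["bn1_rm"]), rv1 = as<vec>(params["bn1_rv"]);
  vec st_m1(c.M2), st_v1(c.M2);
  c.xhat1.set_size(c.M2); c.invstd1.set_size(c.M2);
  c.elu1.set_size(c.M2); c.mask1.set_size(c.M2); c.X1.set_size(c.M2);
  for (int m = 0; m < c.M2; ++m) {
    mat y = bn_map_forward(Z(m), g1(m), b1(m), training, c.frozen,
                           c.frozen ? fx_m1(m) : 0.0, c.frozen ? fx_v1(m) : 0.0,
                           rm1(m), rv1(m),
                           c.xhat1(m), c.invstd1(m), st_m1(m), st_v1(m));
    c.elu1(m) = elu(y);
    mat p = avgpool(c.elu1(m), c.pool1);
    if (c.dropout > 0) {
      c.mask1(m) = dropout_mask(p.n_rows, p.n_cols, c.dropout, rng);
      c.X1(m) = p % c.mask1(m);
    } else {
      c.X1(m) = p;
    }
  }

  // --- Block 2: depthwise temporal convolution ---
  mat wdt = as<mat>(params["wdt"]);            // (K2, M2)
  int K2 = wdt.n_rows, P2 = (K2 - 1) / 2;
  c.U.set_size(c.M2);
  for (int m = 0; m < c.M2; ++m) {
    c.U(m) = mat(c.T1, N, fill::zeros);
    for (int k = 0; k < K2; ++k) {
      int sh = k - P2;
      int t0 = std::max(0, -sh), t1 = std::min(c.T1 - 1, c.T1 - 1 - sh);
      if (t0 > t1) continue;
      c.U(m).rows(t0, t1) += wdt(k, m) * c.X1(m).rows(t0 + sh, t1 + sh);
    }
  }

  // --- Efficient channel attention over the M2 map descriptors ---
  c.Geca = mat(c.M2, N, fill::ones);
  if (c.use_eca) {
    vec we = as<vec>(params["eca_w"]);
    int Ke = we.n_elem, Pe = (Ke - 1) / 2;
    c.D = mat(c.M2, N);
    for (int m = 0; m < c.M2; ++m) c.D.row(m) = mean(c.U(m), 0);
    mat E(c.M2, N, fill::zeros);
    for (int k = 0; k < Ke; ++k) {
      int sh = k - Pe;
      int m0 = std::max(0, -sh), m1 = std::min(c.M2 - 1, c.M2 - 1 - sh);
      if (m0 > m1) continue;
      E.rows(m0, m1) += we(k) * c.D.rows(m0 + sh, m1 + sh);
    }
    c.Geca = sigmoid(E);
  }

  // --- BN2, ELU, pool, dropout ---
  vec g2 = as<vec>(params["bn2_gamma"]), b2 = as<vec>(params["bn2_beta"]);
  vec rm2 = as<vec>(params["bn2_rm"]), rv2 = as<vec>(params["bn2_rv"]);
  vec st_m2(c.M2), st_v2(c.M2);
  c.xhat2.set_size(c.M2); c.invstd2.set_size(c.M2);
  c.elu2.set_size(c.M2); c.mask2.set_size(c.M2);
  c.Fl = mat(c.M2 * c.T2, N);
  for (int m = 0; m < c.M2; ++m) {
    mat Us = c.U(m);
    if (c.use_eca)
      for (int n = 0; n < N; ++n) Us.col(n) *= c.Geca(m, n);
    mat y = bn_map_forward(Us, g2(m), b2(m), training, c.frozen,
                           c.frozen ? fx_m2(m) : 0.0, c.frozen ? fx_v2(m) : 0.0,
                           rm2(m), rv2(m),
                           c.xhat2(m), c.invstd2(m), st_m2(m), st_v2(m));
    c.elu2(m) = elu(y);
    mat p = avgpool(c.elu2(m), c.pool2);
    if (c.dropout > 0) {
      c.mask2(m) = dropout_mask(p.n_rows, p.n_cols, c.dropout, rng);
      p = p % c.mask2(m);
    }
    c.Fl.rows(m * c.T2, m * c.T2 + c.T2 - 1) = p;
  }

  // --- Head: linear map to 1024, batch norm over the batch ---
  mat wd = as<mat>(params["wd"]);              // (M2*T2, 1024)
  vec bd = as<vec>(params["bd"]);
  mat Y = wd.t() * c.Fl;
  Y.each_col() += bd;

  vec g3 = as<vec>(params["bn3_gamma"]), b3 = as<vec>(params["bn3_beta"]);
  vec rm3 = as<vec>(params["bn3_rm"]), rv3 = as<vec>(params["bn3_rv"]);
  int F = Y.n_rows;
  c.xhat3 = mat(F, N); c.invstd3.set_size(F);
  vec mu(F), v(F);
  if (c.frozen) {
    mu = fx_m3; v = fx_v3;
  } else if (training) {
    mu = mean(Y, 1);
    mat Yc = Y;
    Yc.each_col() -= mu;
    v = mean(square(Yc), 1);
    rm3 = (1 - BN_MOMENTUM) * rm3 + BN_MOMENTUM * mu;
    rv3 = (1 - BN_MOMENTUM) * rv3 + BN_MOMENTUM * v;
  } else {
    mu = rm3; v = rv3;
  }
  c.invstd3 = 1.0 / sqrt(v + BN_EPS);
  c.xhat3 = Y;
  c.xhat3.each_col() -= mu;
  c.xhat3.each_col() %= c.invstd3;
  mat out = c.xhat3;
  out.each_col() %= g3;
  out.each_col() += b3;

  List bn_updates = List::create(
    _["bn1_rm"] = rm1, _["bn1_rv"] = rv1,
    _["bn2_rm"] = rm2, _["bn2_rv"] = rv2,
    _["bn3_rm"] = rm3, _["bn3_rv"] = rv3);
  // the statistics this batch was normalized with, reusable as the frozen
  // frame of a paired batch
  List batch_stats = List::create(
    _["bn1_m"] = st_m1, _["bn1_v"] = st_v1,
    _["bn2_m"] = st_m2, _["bn2_v"] = st_v2,
    _["bn3_m"] = mu, _["bn3_v"] = v);

  List res = List::create(
    _["features"] = out.t(),
    _["bn_updates"] = bn_updates,
    _["batch_stats"] = batch_stats,
    _["cache"] = want_cache ? (SEXP)cache : R_NilValue);
  return res;
}

// [[Rcpp::export(name = ".enc_backward")]]
List enc_backward(SEXP cache_ptr, List params, const arma::mat& dFeat) {
  flush_denormals();
  XPtr<EncCache> cp(cache_ptr);
  EncCache& c = *cp;
  const int T = c.T, C = c.C, N = c.N, CN = C * N;
  if (!c.training) stop("backward pass requires a training-mode forward cache");
  if ((int)dFeat.n_rows != N) stop("gradient batch size mismatch");

  List wt = params["wt"];
  cube wsp = as<cube>(params["wsp"]);
  mat wdt = as<mat>(params["wdt"]);
  mat wd = as<mat>(params["wd"]);
  vec g1 = as<vec>(params["bn1_gamma"]);
  vec g2 = as<vec>(params["bn2_gamma"]);
  vec g3 = as<vec>(params["bn3_gamma"]);

  // --- BN3 backward (per feature over the batch) ---
  mat dY = dFeat.t();                          // (1024, N)
  vec dg3 = sum(dY % c.xhat3, 1);
  vec db3 = sum(dY, 1);
  if (c.frozen) {
    dY.each_col() %= g3;
    dY.each_col() %= c.invstd3;
  } else {
    mat dxhat = dY;
    dxhat.each_col() %= g3;
    vec m1 = mean(dxhat, 1);
    vec m2 = mean(dxhat % c.xhat3, 1);
    mat corr = c.xhat3;
    corr.each_col() %= m2;
    dY = dxhat;
    dY.each_col() -= m1;
    dY -= corr;
    dY.each_col() %= c.invstd3;
  }

  // --- Head linear ---
  mat dwd = c.Fl * dY.t();                     // (flat, 1024)
  vec dbd = sum(dY, 1);
  mat dFl = wd * dY;                           // (flat, N)

  // --- Block 2 backward ---
  int K2 = wdt.n_rows, P2 = (K2 - 1) / 2;
  mat dwdt(K2, c.M2, fill::zeros);
  vec dg2v(c.M2), db2v(c.M2);
  mat dGeca(c.M2, N, fill::zeros);
  field<mat> dU(c.M2);                         // grad wrt raw U
  for (int m = 0; m < c.M2; ++m) {
    mat dp = dFl.rows(m * c.T2, m * c.T2 + c.T2 - 1);
    if (c.dropout > 0) dp = dp % c.mask2(m);
    mat de = avgpool_backward(dp, c.pool2, c.T1);
    mat dy = elu_backward(de, c.elu2(m));
    double dgm, dbm;
    mat dUs = bn_map_backward(dy, c.xhat2(m), c.invstd2(m), g2(m), !c.frozen, dgm, dbm);
    dg2v(m) = dgm; db2v(m) = dbm;
    if (c.use_eca) {
      dU(m) = dUs;
      for (int n = 0; n < N; ++n) {
        dGeca(m, n) = dot(dUs.col(n), c.U(m).col(n));
        dU(m).col(n) *= c.Geca(m, n);
      }
    } else {
      dU(m) = dUs;
    }
  }

  vec deca;
  if (c.use_eca) {
    vec we = as<vec>(params["eca_w"]);
    int Ke = we.n_elem, Pe = (Ke - 1) / 2;
    mat dE = dGeca % c.Geca % (1.0 - c.Geca);
    deca = vec(Ke, fill::zeros);
    mat dD(c.M2, N, fill::zeros);
    for (int k = 0; k < Ke; ++k) {
      int sh = k - Pe;
      int m0 = std::max(0, -sh), m1 = std::min(c.M2 - 1, c.M2 - 1 - sh);
      if (m0 > m1) continue;
      deca(k) = accu(dE.rows(m0, m1) % c.D.rows(m0 + sh, m1 + sh));
      dD.rows(m0 + sh, m1 + sh) += we(k) * dE.rows(m0, m1);
    }
    for (int m = 0; m < c.M2; ++m)
      dU(m).each_row() += dD.row(m) / (double)c.T1;
  }

  // depthwise temporal conv backward -> dX1 and kernel grads
  field<mat> dX1(c.M2);
  for (int m = 0; m < c.M2; ++m) {
    dX1(m) = mat(c.T1, N, fill::zeros);
    for (int k = 0; k < K2; ++k) {
      int sh = k - P2;
      int t0 = std::max(0, -sh), t1 = std::min(c.T1 - 1, c.T1 - 1 - sh);
      if (t0 > t1) continue;
      dwdt(k, m) = accu(dU(m).rows(t0, t1) % c.X1(m).rows(t0 + sh, t1 + sh));
      dX1(m).rows(t0 + sh, t1 + sh) += wdt(k, m) * dU(m).rows(t0, t1);
    }
  }

  // --- Block 1 backward: dropout, pool, ELU, BN1 ---
  vec dg1v(c.M2), db1v(c.M2);
  field<mat> dZ(c.M2);
  for (int m = 0; m < c.M2; ++m) {
    mat dp = dX1(m);
    if (c.dropout > 0) dp = dp % c.mask1(m);
    mat de = avgpool_backward(dp, c.pool1, T);
    mat dy = elu_backward(de, c.elu1(m));
    double dgm, dbm;
    dZ(m) = bn_map_backward(dy, c.xhat1(m), c.invstd1(m), g1(m), !c.frozen, dgm, dbm);
    dg1v(m) = dgm; db1v(m) = dbm;
  }

  // --- spatial depthwise conv backward (+ SE gate grads) ---
  cube dwsp(C, c.DM, c.M1, fill::zeros);
  mat dGse(c.M1, N, fill::zeros);
  field<mat> dA1(c.M1);                        // grad wrt raw temporal maps
  for (int m = 0; m < c.M1; ++m) {
    dA1(m) = mat(T, CN, fill::zeros);
    mat W = wsp.slice(m);                      // (C, DM)
    mat Av(c.A1(m).memptr(), (uword)(T * C), (uword)N, false, true);
    mat dAv(dA1(m).memptr(), (uword)(T * C), (uword)N, false, true);
    for (int j = 0; j < c.DM; ++j) {
      mat B = dZ(m * c.DM + j);                // (T, N)
      if (c.use_se) {
        // gate gradient needs the unscaled forward output of this map pair
        mat Yr(T, N, fill::zeros);
        for (int ch = 0; ch < C; ++ch)
          Yr += W(ch, j) * Av.rows(T * ch, T * ch + T - 1);
        dGse.row(m) += sum(B % Yr, 0);
        B.each_row() %= c.Gse.row(m);          // route grads through the gate
      }
      for (int ch = 0; ch < C; ++ch) {
        dwsp(ch, j, m) = accu(B % Av.rows(T * ch, T * ch + T - 1));
        dAv.rows(T * ch, T * ch + T - 1) += W(ch, j) * B;
      }
    }
  }

  // --- SE backward ---
  mat dse_w1, dse_w2; vec dse_b1, dse_b2;
  if (c.use_se) {
    mat se_w1 = as<mat>(params["se_w1"]);
    mat se_w2 = as<mat>(params["se_w2"]);
    mat dL2 = dGse % c.Gse % (1.0 - c.Gse);    // (M1, N)
    dse_w2 = c.H1 * dL2.t();                   // (H, M1)
    dse_b2 = sum(dL2, 1);
    mat dH1 = se_w2 * dL2;                     // (H, N)
    mat dL1 = dH1 % conv_to<mat>::from(c.H1 > 0);
    dse_w1 = c.Ssq * dL1.t();                  // (M1, H)
    dse_b1 = sum(dL1, 1);
    mat dSsq = se_w1 * dL1;                    // (M1, N)
    double scale = 1.0 / (double)(T * C);
    for (int m = 0; m < c.M1; ++m) {
      mat dAv(dA1(m).memptr(), (uword)(T * C), (uword)N, false, true);
      dAv.each_row() += dSsq.row(m) * scale;
    }
  }

  // --- temporal conv backward (kernel grads only; input grads not needed) ---
  // dW = patches_view' * dA1, reusing the forward's cached patch matrix.
  List dwt(c.B);
  int Pmax = (c.patches.n_cols - 1) / 2;
  for (int b = 0; b < c.B; ++b) {
    mat W = as<mat>(wt[b]);
    int K = W.n_rows, o = Pmax - (K - 1) / 2;
    mat dcat(T * CN, c.F1);
    for (int f = 0; f < c.F1; ++f)
      dcat.col(f) = vectorise(dA1(b * c.F1 + f));
    dwt[b] = mat(c.patches.cols(o, o + K - 1).t() * dcat);   // (K, F1)
  }

  List grads = List::create(
    _["wt"] = dwt,
    _["wsp"] = dwsp,
    _["bn1_gamma"] = dg1v, _["bn1_beta"] = db1v,
    _["wdt"] = dwdt,
    _["bn2_gamma"] = dg2v, _["bn2_beta"] = db2v,
    _["wd"] = dwd, _["bd"] = dbd,
    _["bn3_gamma"] = dg3, _["bn3_beta"] = db3);
  if (c.use_se) {
    grads["se_w1"] = dse_w1; grads["se_b1"] = dse_b1;
    grads["se_w2"] = dse_w2; grads["se_b2"] = dse_b2;
  }
  if (c.use_eca) grads["eca_w"] = deca;
  return grads;
}
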