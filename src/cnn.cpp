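// Compact CNN for stacked co-occurrence matrices, written directly on BLAS
// via Armadillo (single precision): conv 3x3/pad 1 as im2col + GEMM,
// batch-norm, ReLU, 2x2 max-pool, two fully connected layers, weighted
// cross-entropy, Adam. All randomness (init, shuffling) comes from R, so a
// run is a pure function of its inputs. The conv1 im2col of every training
// and validation sample is computed once and reused across epochs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

namespace {

struct Net {
  fmat W1; fvec b1, g1, be1, rm1, rv1;
  fmat W2; fvec b2, g2, be2, rm2, rv2;
  fmat W3; fvec b3;
  fmat W4; fvec b4;
};

fmat as_f(const NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  const double* p = REAL(m);
  for (uword i = 0; i < out.n_elem; ++i) out[i] = (float)p[i];
  return out;
}
fvec as_fv(const NumericVector& v) {
  fvec out(v.size());
  for (uword i = 0; i < out.n_elem; ++i) out[i] = (float)v[i];
  return out;
}

Net load_net(const List& w) {
  Net n;
  n.W1 = as_f(w["conv1_w"]); n.b1 = as_fv(w["conv1_b"]);
  n.g1 = as_fv(w["bn1_gamma"]); n.be1 = as_fv(w["bn1_beta"]);
  n.rm1 = as_fv(w["bn1_mean"]); n.rv1 = as_fv(w["bn1_var"]);
  n.W2 = as_f(w["conv2_w"]); n.b2 = as_fv(w["conv2_b"]);
  n.g2 = as_fv(w["bn2_gamma"]); n.be2 = as_fv(w["bn2_beta"]);
  n.rm2 = as_fv(w["bn2_mean"]); n.rv2 = as_fv(w["bn2_var"]);
  n.W3 = as_f(w["fc1_w"]); n.b3 = as_fv(w["fc1_b"]);
  n.W4 = as_f(w["fc2_w"]); n.b4 = as_fv(w["fc2_b"]);
  return n;
}

NumericMatrix to_R(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (uword i = 0; i < m.n_elem; ++i) out[i] = (double)m[i];
  return out;
}
NumericVector to_R(const fvec& v) {
  NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

List dump_net(const Net& n) {
  return List::create(
      _["conv1_w"] = to_R(n.W1), _["conv1_b"] = to_R(n.b1),
      _["bn1_gamma"] = to_R(n.g1), _["bn1_beta"] = to_R(n.be1),
      _["bn1_mean"] = to_R(n.rm1), _["bn1_var"] = to_R(n.rv1),
      _["conv2_w"] = to_R(n.W2), _["conv2_b"] = to_R(n.b2),
      _["bn2_gamma"] = to_R(n.g2), _["bn2_beta"] = to_R(n.be2),
      _["bn2_mean"] = to_R(n.rm2), _["bn2_var"] = to_R(n.rv2),
      _["fc1_w"] = to_R(n.W3), _["fc1_b"] = to_R(n.b3),
      _["fc2_w"] = to_R(n.W4), _["fc2_b"] = to_R(n.b4));
}

// im2col for a 3x3 kernel with padding 1 on an L x L plane per channel.
// src: one sample, C planes of L*L (column-major, row index fastest).
// dst column for spatial position (i, j) holds C*9 values ordered
// (channel, kj, ki); dst has C*9 rows and L*L columns.
void im2col3(const float* src, int C, int L, float* dst) {
  const int L2 = L * L, R = C * 9;
  for (int j = 0; j < L; ++j) {
    for (int i = 0; i < L; ++i) {
      float* col = dst + (size_t)R * (i + (size_t)L * j);
      const bool interior =
          i > 0 && i < L - 1 && j > 0 && j < L - 1;
      for (int c = 0; c < C; ++c) {
        const float* p = src + (size_t)c * L2 + i + (size_t)L * j;
        if (interior) {
          col[0] = p[-L - 1]; col[1] = p[-L]; col[2] = p[-L + 1];
          col[3] = p[-1];     col[4] = p[0];  col[5] = p[1];
          col[6] = p[L - 1];  col[7] = p[L];  col[8] = p[L + 1];
        } else {
          int t = 0;
          for (int kj = -1; kj <= 1; ++kj) {
            const int jj = j + kj;
            for (int ki = -1; ki <= 1; ++ki) {
              const int ii = i + ki;
              col[t++] = (ii >= 0 && ii < L && jj >= 0 && jj < L)
                             ? p[ki + (size_t)L * kj] : 0.0f;
            }
          }
        }
        col += 9;
      }
    }
  }
}

// transpose of im2col3: scatter-add dcol back onto the C x L x L grid
void col2im3(const float* dcol, int C, int L, float* dst) {
  const int L2 = L * L, R = C * 9;
  for (int j = 0; j < L; ++j) {
    for (int i = 0; i < L; ++i) {
      const float* col = dcol + (size_t)R * (i + (size_t)L * j);
      const bool interior = i > 0 && i < L - 1 && j > 0 && j < L - 1;
      for (int c = 0; c < C; ++c) {
        float* p = dst + (size_t)c * L2 + i + (size_t)L * j;
        if (interior) {
          p[-L - 1] += col[0]; p[-L] += col[1]; p[-L + 1] += col[2];
          p[-1] += col[3];     p[0] += col[4];  p[1] += col[5];
          p[L - 1] += col[6];  p[L] += col[7];  p[L + 1] += col[8];
        } else {
          int t = 0;
          for (int kj = -1; kj <= 1; ++kj) {
            const int jj = j + kj;
            for (int ki = -1; ki <= 1; ++ki) {
              const int ii = i + ki;
              if (ii >= 0 && ii < L && jj >= 0 && jj < L)
                p[ki + (size_t)L * kj] += col[t];
              ++t;
            }
          }
        }
        col += 9;
      }
    }
  }
}

// 2x2 max pooling, stride 2. A is (channels x B*L*L) with column
// s*L*L + i + L*j; output (channels x B*(L/2)^2). arg records the winner
// (0..3) for the backward pass.
void maxpool2(const fmat& A, int B, int L, fmat& P, arma::Mat<arma::u8>& arg) {
  const int Lh = L / 2, L2 = L * L, Q = Lh * Lh;
  const uword C = A.n_rows;
  P.set_size(C, (uword)B * Q);
  arg.set_size(C, (uword)B * Q);
  for (int s = 0; s < B; ++s) {
    for (int j2 = 0; j2 < Lh; ++j2) {
      for (int i2 = 0; i2 < Lh; ++i2) {
        const uword oc = (uword)s * Q + i2 + (uword)Lh * j2;
        const uword c00 = (uword)s * L2 + 2 * i2 + (uword)L * (2 * j2);
        const float* a0 = A.colptr(c00);
        const float* a1 = A.colptr(c00 + 1);
        const float* a2 = A.colptr(c00 + L);
        const float* a3 = A.colptr(c00 + L + 1);
        float* po = P.colptr(oc);
        arma::u8* ao = arg.colptr(oc);
        for (uword c = 0; c < C; ++c) {
          float best = a0[c]; arma::u8 bi = 0;
          if (a1[c] > best) { best = a1[c]; bi = 1; }
          if (a2[c] > best) { best = a2[c]; bi = 2; }
          if (a3[c] > best) { best = a3[c]; bi = 3; }
          po[c] = best; ao[c] = bi;
        }
      }
    }
  }
}

void maxpool2_back(const fmat& dP, const arma::Mat<arma::u8>& arg, int B,
                   int L, fmat& dA) {
  const int Lh = L / 2, L2 = L * L, Q = Lh * Lh;
  const uword C = dP.n_rows;
  dA.zeros(C, (uword)B * L2);
  for (int s = 0; s < B; ++s) {
    for (int j2 = 0; j2 < Lh; ++j2) {
      for (int i2 = 0; i2 < Lh; ++i2) {
        const uword oc = (uword)s * Q + i2 + (uword)Lh * j2;
        const uword c00 = (uword)s * L2 + 2 * i2 + (uword)L * (2 * j2);
        float* d0 = dA.colptr(c00);
        float* d1 = dA.colptr(c00 + 1);
        float* d2 = dA.colptr(c00 + L);
        float* d3 = dA.colptr(c00 + L + 1);
        const float* dp = dP.colptr(oc);
        const arma::u8* ao = arg.colptr(oc);
        for (uword c = 0; c < C; ++c) {
          switch (ao[c]) {
            case 0: d0[c] += dp[c]; break;
            case 1: d1[c] += dp[c]; break;
            case 2: d2[c] += dp[c]; break;
            default: d3[c] += dp[c]; break;
          }
        }
      }
    }
  }
}

struct BNCache { fvec invstd; fmat xhat; };

// train-mode batch norm over rows (channels) fused with bias add and ReLU:
// Z holds the pre-norm conv output and becomes the ReLU activation; xhat is
// kept for the backward pass. Running stats use momentum `mom` and the
// unbiased variance, the usual convention.
void bn_relu_train(fmat& Z, const fvec& b, const fvec& g, const fvec& be,
                   fvec& rm, fvec& rv, float mom, BNCache& cache) {
  const float eps = 1e-5f;
  const uword C = Z.n_rows, N = Z.n_cols;
  Z.each_col() += b;
  fvec mu = arma::mean(Z, 1);
  fvec var(C);
  // centered second moment, single fused pass
  {
    fvec acc(C, arma::fill::zeros);
    for (uword j = 0; j < N; ++j) {
      const float* z = Z.colptr(j);
      float* a = acc.memptr();
      const float* m = mu.memptr();
      for (uword c = 0; c < C; ++c) {
        const float d = z[c] - m[c];
        a[c] += d * d;
      }
    }
    var = acc / (float)N;
  }
  cache.invstd = 1.0f / arma::sqrt(var + eps);
  cache.xhat.set_size(C, N);
  for (uword j = 0; j < N; ++j) {
    float* z = Z.colptr(j);
    float* xh = cache.xhat.colptr(j);
    const float* m = mu.memptr();
    const float* is = cache.invstd.memptr();
    const float* gg = g.memptr();
    const float* bb = be.memptr();
    for (uword c = 0; c < C; ++c) {
      const float x = (z[c] - m[c]) * is[c];
      xh[c] = x;
      const float y = gg[c] * x + bb[c];
      z[c] = y > 0.0f ? y : 0.0f;
    }
  }
  const float corr = (float)((double)N / std::max(1.0, (double)N - 1.0));
  rm = (1.0f - mom) * rm + mom * mu;
  rv = (1.0f - mom) * rv + mom * (var * corr);
}

void bn_relu_eval(fmat& Z, const fvec& b, const fvec& g, const fvec& be,
                  const fvec& rm, const fvec& rv) {
  const float eps = 1e-5f;
  const uword C = Z.n_rows, N = Z.n_cols;
  fvec scale = g / arma::sqrt(rv + eps);
  fvec shift = be - (rm - b) % scale;
  for (uword j = 0; j < N; ++j) {
    float* z = Z.colptr(j);
    const float* sc = scale.memptr();
    const float* sh = shift.memptr();
    for (uword c = 0; c < C; ++c) {
      const float y = sc[c] * z[c] + sh[c];
      z[c] = y > 0.0f ? y : 0.0f;
    }
  }
}

// fused ReLU-mask + batch-norm backward: dY is the gradient at the ReLU
// output (A = post-ReLU activation); on exit dY holds the gradient at the
// pre-norm conv output. Two passes over the matrices.
void bn_relu_backward(fmat& dY, const fmat& A, const BNCache& cache,
                      const fvec& g, fvec& dg, fvec& dbe) {
  const uword C = dY.n_rows, N = dY.n_cols;
  dg.zeros(C);
  dbe.zeros(C);
  for (uword j = 0; j < N; ++j) {
    float* d = dY.colptr(j);
    const float* a = A.colptr(j);
    const float* xh = cache.xhat.colptr(j);
    float* pg = dg.memptr();
    float* pb = dbe.memptr();
    for (uword c = 0; c < C; ++c) {
      const float dd = a[c] > 0.0f ? d[c] : 0.0f;
      d[c] = dd;
      pg[c] += dd * xh[c];
      pb[c] += dd;
    }
  }
  // dxhat = dY * gamma; dZ = invstd/N * (N*dxhat - dbeta*gamma... ) folded:
  // dZ = invstd/N * (N*g*dY - g*dbe - xhat * g*dg)
  const float Nf = (float)N;
  fvec a1 = (g % cache.invstd);                  // per-row multiplier
  fvec a2 = (g % dbe) % (cache.invstd / Nf);     // constant term
  fvec a3 = (g % dg) % (cache.invstd / Nf);      // xhat term
  for (uword j = 0; j < N; ++j) {
    float* d = dY.colptr(j);
    const float* xh = cache.xhat.colptr(j);
    const float* p1 = a1.memptr();
    const float* p2 = a2.memptr();
    const float* p3 = a3.memptr();
    for (uword c = 0; c < C; ++c)
      d[c] = p1[c] * d[c] - p2[c] - p3[c] * xh[c];
  }
}

double auc_rank(const std::vector<double>& score, const IntegerVector& y) {
  const int n = (int)score.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return score[a] < score[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score[idx[j + 1]] == score[idx[i]]) ++j;
    const double r = 0.5 * (i + j) + 1.0;
    for (int t = i; t <= j; ++t) rank[idx[t]] = r;
    i = j + 1;
  }
  double rsum = 0; long npos = 0;
  for (int t = 0; t < n; ++t)
    if (y[t] == 1) { rsum += rank[t]; ++npos; }
  const long nneg = n - npos;
  if (npos == 0 || nneg == 0) return NA_REAL;
  return (rsum - npos * (npos + 1.0) / 2.0) / ((double)npos * nneg);
}

struct Cache {
  fmat A1, P1, Xcol2, A2, P2, F, H, Prob;
  arma::Mat<arma::u8> arg1, arg2;
  BNCache bn1, bn2;
};

// Forward over one batch. `col1` holds precomputed conv1 im2col blocks
// (C*9 rows, one L*L-column block per dataset sample); `sel` indexes
// samples within it.
void forward(const fmat& col1, const arma::uvec& sel, Net& net, int C, int L,
             bool train, float bn_mom, Cache& ca) {
  const int B = (int)sel.n_elem, L2 = L * L, Lh = L / 2, Lq = L / 4;
  const int C2 = (int)net.W1.n_rows;
  fmat Z1(C2, (uword)B * L2);
  for (int s = 0; s < B; ++s)
    Z1.cols((uword)s * L2, (uword)(s + 1) * L2 - 1) =
        net.W1 * col1.cols((uword)sel[s] * L2, (uword)(sel[s] + 1) * L2 - 1);
  if (train) bn_relu_train(Z1, net.b1, net.g1, net.be1, net.rm1, net.rv1,
                           bn_mom, ca.bn1);
  else bn_relu_eval(Z1, net.b1, net.g1, net.be1, net.rm1, net.rv1);
  ca.A1 = std::move(Z1);
  maxpool2(ca.A1, B, L, ca.P1, ca.arg1);

  ca.Xcol2.set_size(C2 * 9, (uword)B * Lh * Lh);
  for (int s = 0; s < B; ++s)
    im2col3(ca.P1.colptr((uword)s * Lh * Lh), C2, Lh,
            ca.Xcol2.colptr((uword)s * Lh * Lh));
  fmat Z2 = net.W2 * ca.Xcol2;
  if (train) bn_relu_train(Z2, net.b2, net.g2, net.be2, net.rm2, net.rv2,
                           bn_mom, ca.bn2);
  else bn_relu_eval(Z2, net.b2, net.g2, net.be2, net.rm2, net.rv2);
  ca.A2 = std::move(Z2);
  maxpool2(ca.A2, B, Lh, ca.P2, ca.arg2);

  const uword Q = (uword)Lq * Lq;
  const uword C3 = net.W2.n_rows;
  ca.F.set_size(C3 * Q, B);
  for (int s = 0; s < B; ++s)
    std::memcpy(ca.F.colptr(s), ca.P2.colptr((uword)s * Q),
                sizeof(float) * C3 * Q);
  fmat Z3 = net.W3 * ca.F;
  Z3.each_col() += net.b3;
  ca.H = arma::clamp(Z3, 0.0f, std::numeric_limits<float>::max());
  fmat O = net.W4 * ca.H;
  O.each_col() += net.b4;
  O.each_row() -= arma::max(O, 0);  // stabilized column softmax
  O = arma::exp(O);
  arma::frowvec tot = arma::sum(O, 0);
  O.each_row() /= tot;
  ca.Prob = std::move(O);
}

struct Grads {
  fmat W1, W2, W3, W4;
  fvec b1, b2, b3, b4, g1, be1, g2, be2;
};

void backward(const fmat& col1, const arma::uvec& sel, const IntegerVector& y,
              const fvec& class_w, Net& net, int C, int L, Cache& ca,
              Grads& gr) {
  const int B = (int)sel.n_elem, L2 = L * L, Lh = L / 2, Lq = L / 4;
  const uword Q = (uword)Lq * Lq;
  fmat dO = ca.Prob;  // softmax + weighted CE gradient
  for (int s = 0; s < B; ++s) {
    const int ys = y[sel[s]];
    dO(ys, s) -= 1.0f;
    dO.col(s) *= class_w[ys] / (float)B;
  }
  gr.W4 = dO * ca.H.t();
  gr.b4 = arma::sum(dO, 1);
  fmat dH = net.W4.t() * dO;
  {
    float* d = dH.memptr();
    const float* h = ca.H.memptr();
    for (uword i = 0; i < dH.n_elem; ++i)
      if (h[i] == 0.0f) d[i] = 0.0f;
  }
  gr.W3 = dH * ca.F.t();
  gr.b3 = arma::sum(dH, 1);
  fmat dF = net.W3.t() * dH;

  const uword C3 = net.W2.n_rows;
  fmat dP2(C3, (uword)B * Q);
  for (int s = 0; s < B; ++s)
    std::memcpy(dP2.colptr((uword)s * Q), dF.colptr(s),
                sizeof(float) * C3 * Q);
  fmat dA2;
  maxpool2_back(dP2, ca.arg2, B, Lh, dA2);
  bn_relu_backward(dA2, ca.A2, ca.bn2, net.g2, gr.g2, gr.be2);
  gr.b2 = arma::sum(dA2, 1);
  gr.W2 = dA2 * ca.Xcol2.t();
  fmat dXcol2 = net.W2.t() * dA2;
  const int C2 = (int)net.W1.n_rows;
  fmat dP1(C2, (uword)B * Lh * Lh, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    col2im3(dXcol2.colptr((uword)s * Lh * Lh), C2, Lh,
            dP1.colptr((uword)s * Lh * Lh));
  fmat dA1;
  maxpool2_back(dP1, ca.arg1, B, L, dA1);
  bn_relu_backward(dA1, ca.A1, ca.bn1, net.g1, gr.g1, gr.be1);
  gr.b1 = arma::sum(dA1, 1);
  gr.W1.zeros(net.W1.n_rows, net.W1.n_cols);
  for (int s = 0; s < B; ++s)
    gr.W1 += dA1.cols((uword)s * L2, (uword)(s + 1) * L2 - 1) *
             col1.cols((uword)sel[s] * L2, (uword)(sel[s] + 1) * L2 - 1).t();
}

// fused elementwise Adam step (single pass per tensor)
void adam_upd(float* w, const float* g, float* m, float* v, size_t n,
              float lr, float b1, float b2, long t) {
  const float bc1 = 1.0f - std::pow(b1, (float)t);
  const float bc2 = 1.0f - std::pow(b2, (float)t);
  for (size_t i = 0; i < n; ++i) {
    const float mi = b1 * m[i] + (1.0f - b1) * g[i];
    const float vi = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
    m[i] = mi;
    v[i] = vi;
    w[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + 1e-8f);
  }
}

struct Adam {
  std::vector<fmat> mM, vM;
  std::vector<fvec> mV, vV;
  long t = 0;
  void init(const Net& n) {
    for (const fmat* w : {&n.W1, &n.W2, &n.W3, &n.W4}) {
      mM.emplace_back(w->n_rows, w->n_cols, arma::fill::zeros);
      vM.emplace_back(w->n_rows, w->n_cols, arma::fill::zeros);
    }
    for (const fvec* w : {&n.b1, &n.b2, &n.b3, &n.b4, &n.g1, &n.be1, &n.g2,
                          &n.be2}) {
      mV.emplace_back(w->n_elem, arma::fill::zeros);
      vV.emplace_back(w->n_elem, arma::fill::zeros);
    }
  }
  void step(Net& n, Grads& g, float lr, float b1, float b2) {
    ++t;
    fmat* Ws[4] = {&n.W1, &n.W2, &n.W3, &n.W4};
    fmat* Gs[4] = {&g.W1, &g.W2, &g.W3, &g.W4};
    for (int i = 0; i < 4; ++i)
      adam_upd(Ws[i]->memptr(), Gs[i]->memptr(), mM[i].memptr(),
               vM[i].memptr(), Ws[i]->n_elem, lr, b1, b2, t);
    fvec* ws[8] = {&n.b1, &n.b2, &n.b3, &n.b4, &n.g1, &n.be1, &n.g2, &n.be2};
    fvec* gs[8] = {&g.b1, &g.b2, &g.b3, &g.b4, &g.g1, &g.be1, &g.g2, &g.be2};
    for (int i = 0; i < 8; ++i)
      adam_upd(ws[i]->memptr(), gs[i]->memptr(), mV[i].memptr(),
               vV[i].memptr(), ws[i]->n_elem, lr, b1, b2, t);
  }
};

// conv1 im2col of every sample, built once: (C*9) x (n * L*L)
fmat build_col1(const NumericMatrix& X, int C, int L) {
  const int n = X.ncol(), L2 = L * L;
  if (X.nrow() != C * L2) stop("input rows must equal C * L * L");
  fmat col(C * 9, (uword)n * L2);
  std::vector<float> sample(C * L2);
  for (int s = 0; s < n; ++s) {
    const double* src = &X(0, s);
    for (int i = 0; i < C * L2; ++i) sample[i] = (float)src[i];
    im2col3(sample.data(), C, L, col.colptr((uword)s * L2));
  }
  return col;
}

std::vector<double> scores_eval(const fmat& col1, int n, Net& net, int C,
                                int L, int batch) {
  std::vector<double> out(n);
  Cache ca;
  for (int start = 0; start < n; start += batch) {
    const int end = std::min(n, start + batch);
    arma::uvec sel(end - start);
    for (int s = start; s < end; ++s) sel[s - start] = s;
    forward(col1, sel, net, C, L, false, 0.1f, ca);
    for (int s = start; s < end; ++s) out[s] = (double)ca.Prob(1, s - start);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(const NumericMatrix& Xtr, const IntegerVector& ytr,
                   const NumericMatrix& Xval, const IntegerVector& yval,
                   const List& init, const NumericVector& class_w, int C,
                   int L, int epochs, int batch_size, double lr, double beta1,
                   double beta2, const IntegerMatrix& order) {
  Net net = load_net(init);
  Adam opt;
  opt.init(net);
  const fmat col_tr = build_col1(Xtr, C, L);
  const fmat col_val = build_col1(Xval, C, L);
  fvec cw = as_fv(class_w);
  const int n = Xtr.ncol(), n_val = Xval.ncol();
  if (order.nrow() != epochs || order.ncol() != n)
    stop("order must be epochs x n_train");

  NumericVector ep_loss(epochs), ep_auc(epochs);
  double best_auc = -1.0;
  int best_epoch = 0;
  Net best = net;
  Cache ca;
  Grads gr;
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0;
    long n_seen = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(n, start + batch_size);
      arma::uvec sel(end - start);
      for (int s = start; s < end; ++s) sel[s - start] = order(e, s) - 1;
      forward(col_tr, sel, net, C, L, true, 0.1f, ca);
      for (uword s = 0; s < sel.n_elem; ++s) {
        const int ys = ytr[sel[s]];
        const double p = std::max((double)ca.Prob(ys, s), 1e-12);
        loss_sum += -std::log(p) * cw[ys];
      }
      n_seen += sel.n_elem;
      backward(col_tr, sel, ytr, cw, net, C, L, ca, gr);
      opt.step(net, gr, (float)lr, (float)beta1, (float)beta2);
    }
    ep_loss[e] = loss_sum / n_seen;
    std::vector<double> vs = scores_eval(col_val, n_val, net, C, L, batch_size);
    const double va = auc_rank(vs, yval);
    ep_auc[e] = va;
    if (!ISNA(va) && va > best_auc) { best_auc = va; best_epoch = e + 1; best = net; }
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch == 0) { best = net; best_epoch = epochs; }
  return List::create(_["weights"] = dump_net(best),
                      _["final_weights"] = dump_net(net),
                      _["train_loss"] = ep_loss, _["val_auc"] = ep_auc,
                      _["best_epoch"] = best_epoch, _["best_val_auc"] = best_auc);
}

// [[Rcpp::export]]
NumericVector cnn_forward_cpp(const NumericMatrix& Xin, const List& w, int C,
                              int L, int batch_size) {
  Net net = load_net(w);
  const fmat col = build_col1(Xin, C, L);
  std::vector<double> s = scores_eval(col, Xin.ncol(), net, C, L, batch_size);
  return NumericVector(s.begin(), s.end());
}
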